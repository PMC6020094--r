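endpoint,task,unit,suggestion,reference
LogS,regression,log mol/L,"Aqueous solubility above -4 log mol/L is generally adequate for oral absorption.","Delaney JS. J Chem Inf Comput Sci. 2004"
LogD7.4,regression,log ratio,"LogD at pH 7.4 between 1 and 3 balances permeability and solubility.","Waring MJ. Expert Opin Drug Discov. 2010"
Caco-2,regression,log cm/s,"Caco-2 permeability above -5.15 log cm/s suggests good intestinal absorption.","Hou T et al. J Chem Inf Model. 2007"
PPB,regression,%,"Plasma protein binding above 90% narrows the free-drug window; check dosing.","Smith DA et al. Nat Rev Drug Discov. 2010"
VD,regression,L/kg,"Volumes of distribution between 0.04 and 20 L/kg are typical for marketed drugs.","Lombardo F et al. J Med Chem. 2002"
CL,regression,mL/min/kg,"Clearance below 15 mL/min/kg is usually compatible with once-daily dosing.","Obach RS et al. Drug Metab Dispos. 2008"
T1/2,regression,h,"Half-life above 3 h generally supports practical dosing intervals.","Obach RS et al. Drug Metab Dispos. 2008"
HIA,classification,,"Predicted poor intestinal absorption; consider polarity or formulation work.","Hou T et al. J Chem Inf Model. 2007"
BBB,classification,,"Blood-brain-barrier penetration matters for CNS targets and CNS side effects.","Martins IF et al. J Chem Inf Model. 2012"
Pgp-inhibitor,classification,,"P-glycoprotein inhibition may cause drug-drug interactions.","Broccatelli F et al. J Med Chem. 2011"
Pgp-substrate,classification,,"P-glycoprotein substrates can show limited brain exposure and efflux.","Broccatelli F et al. J Med Chem. 2011"
CYP1A2-inhibitor,classification,,"CYP1A2 inhibition may perturb co-medication exposure.","Veith H et al. Nat Biotechnol. 2009"
CYP3A4-inhibitor,classification,,"CYP3A4 inhibition is a common source of clinical drug-drug interactions.","Veith H et al. Nat Biotechnol. 2009"
hERG,classification,,"Predicted hERG blockade flags cardiotoxicity risk; confirm with patch clamp.","Wang S et al. Mol Pharm. 2016"
Ames,classification,,"Ames positivity flags mutagenicity; inspect for reactive substructures.","Xu C et al. J Chem Inf Model. 2012"
DILI,classification,,"Drug-induced liver injury risk; review dose and reactive metabolite liability.","Xu Y et al. Chem Res Toxicol. 2015"
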