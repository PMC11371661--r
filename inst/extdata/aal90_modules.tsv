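#region	module
PreCG.L	auditory_motor
PreCG.R	auditory_motor
ROL.L	auditory_motor
ROL.R	auditory_motor
SMA.L	auditory_motor
SMA.R	auditory_motor
PoCG.L	auditory_motor
PoCG.R	auditory_motor
SMG.L	auditory_motor
SMG.R	auditory_motor
PCL.L	auditory_motor
PCL.R	auditory_motor
HES.L	auditory_motor
HES.R	auditory_motor
STG.L	auditory_motor
STG.R	auditory_motor
TPOsup.L	auditory_motor
TPOsup.R	auditory_motor
MTG.L	auditory_motor
MTG.R	auditory_motor
CAL.L	vision
CAL.R	vision
CUN.L	vision
CUN.R	vision
LING.L	vision
LING.R	vision
SOG.L	vision
SOG.R	vision
MOG.L	vision
MOG.R	vision
IOG.L	vision
IOG.R	vision
FFG.L	vision
FFG.R	vision
MFG.L	attention
MFG.R	attention
ORBmid.L	attention
ORBmid.R	attention
IFGoperc.L	attention
IFGoperc.R	attention
IFGtriang.L	attention
IFGtriang.R	attention
INS.L	attention
INS.R	attention
SPG.L	attention
SPG.R	attention
IPL.L	attention
IPL.R	attention
ANG.L	attention
ANG.R	attention
ITG.L	attention
ITG.R	attention
SFGdor.L	dmn
SFGdor.R	dmn
ORBsup.L	dmn
ORBsup.R	dmn
ORBinf.L	dmn
ORBinf.R	dmn
SFGmed.L	dmn
SFGmed.R	dmn
ORBsupmed.L	dmn
ORBsupmed.R	dmn
ACG.L	dmn
ACG.R	dmn
PCG.L	dmn
PCG.R	dmn
PCUN.L	dmn
PCUN.R	dmn
TPOmid.L	dmn
TPOmid.R	dmn
OLF.L	limbic_subcortical
OLF.R	limbic_subcortical
REC.L	limbic_subcortical
REC.R	limbic_subcortical
DCG.L	limbic_subcortical
DCG.R	limbic_subcortical
HIP.L	limbic_subcortical
HIP.R	limbic_subcortical
PHG.L	limbic_subcortical
PHG.R	limbic_subcortical
AMYG.L	limbic_subcortical
AMYG.R	limbic_subcortical
CAU.L	limbic_subcortical
CAU.R	limbic_subcortical
PUT.L	limbic_subcortical
PUT.R	limbic_subcortical
PAL.L	limbic_subcortical
PAL.R	limbic_subcortical
THA.L	limbic_subcortical
THA.R	limbic_subcortical
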