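roi	network
frontoinsula.L	salience
frontoinsula.R	salience
dACC	salience
TPJ.L	salience
TPJ.R	salience
inferotemporal.L	salience
inferotemporal.R	salience
precentral.L	salience
precentral.R	salience
dlPFC.L	salience
dlPFC.R	salience
IFG.L	salience
IFG.R	salience
orbital.frontoinsula.L	executive
dlPFC.exec.R	executive
dlPFC.exec.L	executive
vlPFC.R	executive
vlPFC.L	executive
frontal.operculum.R	executive
FEF.R	executive
FEF.L	executive
dmPFC	executive
lat.parietal.exec.R	executive
lat.parietal.exec.L	executive
inf.temporal.exec.R	executive
PCC	task_negative
retrosplenial	task_negative
lat.parietal.L	task_negative
lat.parietal.R	task_negative
mPFC.L	task_negative
mPFC.R	task_negative
sup.frontal.L	task_negative
sup.frontal.R	task_negative
inf.temporal.L	task_negative
inf.temporal.R	task_negative
parahippocampal.L	task_negative
parahippocampal.R	task_negative
amygdala.CM.L	subcortical
amygdala.CM.R	subcortical
amygdala.lat.L	subcortical
amygdala.lat.R	subcortical
PAG.L	subcortical
PAG.R	subcortical
habenula.L	subcortical
habenula.R	subcortical
BST.L	subcortical
BST.R	subcortical
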