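code,group,description
K92.2,clin_sig,"Gastrointestinal hemorrhage, unspecified"
R31,clin_sig,"Hematuria, unspecified"
K26.4,clin_sig,"Duodenal ulcer, acute with hemorrhage"
K92.0,clin_sig,Hematemesis
K92.1,clin_sig,Melena
R04.0,clin_sig,Epistaxis
D62,clin_sig,Acute posthemorrhagic anemia
R58,clin_sig,"Hemorrhage, not elsewhere classified"
R57.1,severe,Hypovolemic shock due to hemorrhage
I85.3,severe,Esophageal varices with bleeding
I60,severe,Subarachnoid hemorrhage
I61,severe,Intracerebral hemorrhage
I62,severe,Other nontraumatic intracranial hemorrhage
G95.1,severe,Vascular myelopathies (intraspinal hemorrhage)
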