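label,level,split,count,pct
IRRELEVANT,sentence,train,45897,97.45
ANTECEDENT,sentence,train,154,0.33
CLIN_SIG,sentence,train,900,1.91
SEVERE,sentence,train,149,0.32
IRRELEVANT,sentence,test,18118,97.38
ANTECEDENT,sentence,test,58,0.31
CLIN_SIG,sentence,test,373,2.00
SEVERE,sentence,test,57,0.31
IRRELEVANT,document,train,103,36.79
ANTECEDENT,document,train,67,23.93
CLIN_SIG,document,train,141,50.36
SEVERE,document,train,77,27.50
IRRELEVANT,document,test,44,36.67
ANTECEDENT,document,test,22,18.33
CLIN_SIG,document,test,60,50.00
SEVERE,document,test,31,25.83
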