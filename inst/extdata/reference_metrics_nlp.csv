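metric,IRRELEVANT,ANTECEDENT,CLIN_SIG,SEVERE,macro,micro
accuracy,0.83,0.68,0.86,0.89,0.81,0.84
precision,0.81,0.72,0.87,0.92,0.83,0.85
recall,0.98,0.88,0.59,0.31,0.69,0.71
f1,0.89,0.65,0.88,0.70,0.78,0.80
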