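metric,value
accuracy_pct,93.7
recall_pct,89.2
precision_pct,85.1
auc,0.91
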