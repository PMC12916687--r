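{"FP1":1,"FPZ":1,"FP2":1,"AF3":2,"AF4":2,"F7":3,"F5":3,"F3":3,"F1":3,"FZ":4,"F2":5,"F4":5,"F6":5,"F8":5,"FT7":6,"FC5":7,"FC3":7,"FC1":7,"FCZ":7,"FC2":7,"FC4":7,"FC6":7,"FT8":8,"T7":12,"C5":9,"C3":9,"C1":9,"CZ":10,"C2":11,"C4":11,"C6":11,"T8":12,"TP7":13,"CP5":13,"CP3":13,"CP1":13,"CPZ":13,"CP2":13,"CP4":13,"CP6":13,"TP8":13,"P7":14,"P5":14,"P3":14,"P1":14,"PZ":15,"P2":16,"P4":16,"P6":16,"P8":16,"PO7":17,"PO5":17,"PO3":17,"POZ":17,"PO4":17,"PO6":17,"PO8":17,"CB1":17,"O1":17,"OZ":17,"O2":17,"CB2":17}
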