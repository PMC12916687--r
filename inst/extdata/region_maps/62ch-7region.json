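{"FP1":1,"FPZ":1,"FP2":1,"AF3":1,"AF4":1,"F7":1,"F5":1,"F3":1,"F1":1,"FZ":1,"F2":1,"F4":1,"F6":1,"F8":1,"FT7":2,"FC5":2,"FC3":2,"FC1":2,"FCZ":2,"FC2":2,"FC4":2,"FC6":2,"FT8":2,"T7":4,"C5":3,"C3":3,"C1":3,"CZ":3,"C2":3,"C4":3,"C6":3,"T8":4,"TP7":4,"CP5":5,"CP3":5,"CP1":5,"CPZ":5,"CP2":5,"CP4":5,"CP6":5,"TP8":4,"P7":6,"P5":6,"P3":6,"P1":6,"PZ":6,"P2":6,"P4":6,"P6":6,"P8":6,"PO7":7,"PO5":7,"PO3":7,"POZ":7,"PO4":7,"PO6":7,"PO8":7,"CB1":7,"O1":7,"OZ":7,"O2":7,"CB2":7}
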