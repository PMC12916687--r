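{"FP1":1,"FPZ":2,"FP2":3,"AF3":1,"AF4":3,"F7":1,"F5":1,"F3":1,"F1":1,"FZ":2,"F2":3,"F4":3,"F6":3,"F8":3,"FT7":4,"FC5":4,"FC3":4,"FC1":4,"FCZ":4,"FC2":4,"FC4":4,"FC6":4,"FT8":4,"T7":6,"C5":5,"C3":5,"C1":5,"CZ":5,"C2":5,"C4":5,"C6":5,"T8":7,"TP7":6,"CP5":8,"CP3":8,"CP1":8,"CPZ":8,"CP2":8,"CP4":8,"CP6":8,"TP8":7,"P7":9,"P5":9,"P3":9,"P1":9,"PZ":9,"P2":9,"P4":9,"P6":9,"P8":9,"PO7":10,"PO5":10,"PO3":10,"POZ":10,"PO4":10,"PO6":10,"PO8":10,"CB1":10,"O1":10,"OZ":10,"O2":10,"CB2":10}
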