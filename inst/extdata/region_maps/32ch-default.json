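{"FP1":1,"FP2":1,"FZ":1,"F3":1,"F4":1,"F7":1,"F8":1,"FC1":2,"FC2":2,"FC5":2,"FC6":2,"CZ":3,"C3":3,"C4":3,"T7":4,"T8":4,"CP1":5,"CP2":5,"CP5":5,"CP6":5,"PZ":6,"P3":6,"P4":6,"P7":6,"P8":6,"PO3":7,"PO4":7,"PO7":7,"PO8":7,"OZ":7,"O1":7,"O2":7}
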