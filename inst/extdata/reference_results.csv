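dataset,method,acc_mean,acc_sd,n_folds
SEED,KNN,49.26,14.89,15
SEED,SVM,51.68,17.86,15
SEED,DGCNN,72.48,14.89,15
SEED,RGNN,79.07,14.82,15
SEED,DMATN,77.29,15.46,15
SEED,TSception,66.22,18.11,15
SEED,TCN,76.54,14.08,15
SEED,PGCN,75.87,18.36,15
SEED,LSTM,73.39,15.88,15
SEED,BiDANN,79.39,16.45,15
SEED,EmT,80.20,11.50,15
SEED,MSGM,83.43,11.42,15
THU-EP,KNN,23.45,4.82,10
THU-EP,SVM,24.72,5.91,10
THU-EP,DGCNN,56.71,3.37,10
THU-EP,RGNN,57.23,3.07,10
THU-EP,DMATN,60.34,5.41,10
THU-EP,TSception,59.18,5.93,10
THU-EP,TCN,57.79,3.13,10
THU-EP,PGCN,56.92,4.31,10
THU-EP,LSTM,55.83,3.52,10
THU-EP,BiDANN,61.44,5.51,10
THU-EP,EmT,59.50,4.70,10
THU-EP,MSGM,62.39,3.13,10
FACED,KNN,22.71,5.34,10
FACED,SVM,25.58,7.43,10
FACED,DGCNN,56.26,4.55,10
FACED,RGNN,58.71,5.05,10
FACED,DMATN,61.41,4.91,10
FACED,TSception,61.92,8.81,10
FACED,TCN,55.26,3.56,10
FACED,PGCN,55.77,7.81,10
FACED,LSTM,56.84,6.31,10
FACED,BiDANN,63.36,7.01,10
FACED,EmT,60.80,6.50,10
FACED,MSGM,63.17,3.62,10
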