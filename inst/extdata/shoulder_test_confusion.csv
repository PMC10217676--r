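label_id,label,TP,TN,FP,FN,threshold
1,humerus,3,60,0,0,0.97
2,scapula,3,59,1,0,0.94
3,supraspinatus,2,59,2,0,0.92
4,subscapularis,3,58,2,0,0.91
5,infraspinatus,4,58,1,0,0.93
6,teres_minor,3,43,17,0,0.94
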