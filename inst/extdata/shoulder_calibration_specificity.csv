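label_id,label,DCM_TTA,DCA,DCA_TTA,DCA_TTA_N10_p05,DCA_TTA_N15_p05
1,humerus,0.98,1.00,1.00,1.00,1.00
2,scapula,0.41,0.76,0.57,0.54,0.54
3,supraspinatus,0.91,0.93,0.98,0.98,0.98
4,subscapularis,0.92,0.94,0.94,0.96,0.98
5,infraspinatus,0.84,0.84,0.84,0.84,0.82
6,teres_minor,0.59,0.50,0.53,0.50,0.53
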