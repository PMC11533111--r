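parameter,man,woman,units,source
BW,73,60,kg,Reference body weight for European adults
W_liver,1.898,1.56,kg,Derived: 2.6% of body weight
W_blood,5.3,3.9,kg,Set equal to blood volume (density 1 kg/L)
W_others,65.802,54.54,kg,Derived: BW - W_liver - W_blood
QC,6.5,5.9,L/min,Reference cardiac output for adults
Q_liver_total,1.6575,1.593,L/min,Derived: 25.5% (men) / 27.0% (women) of cardiac output; portal vein plus hepatic artery
Q_others,4.8425,4.307,L/min,Derived: QC - Q_liver_total
V_blood,5.3,3.9,L,Reference total blood volume for adults
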