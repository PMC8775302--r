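[{"species":"hake","design":"SMP_TS","L50":37.07,"L50_lo":21.22,"L50_hi":37.1,"SR":0.1,"SR_lo":0.1,"SR_hi":7.42,"C":0.01,"C_lo":0,"C_hi":0.02,"p_value":0.972,"deviance":59.29,"dof":82},{"species":"hake","design":"SMP_TL","L50":32.07,"L50_lo":31.04,"L50_hi":32.1,"SR":0.1,"SR_lo":0.1,"SR_hi":0.1,"C":0.02,"C_lo":0.01,"C_hi":0.03,"p_value":0.05,"deviance":102.44,"dof":81},{"species":"hake","design":"SMP_BS","L50":35.03,"L50_lo":0.1,"L50_hi":35.09,"SR":0.1,"SR_lo":0.1,"SR_hi":27.08,"C":0.05,"C_lo":0.02,"C_hi":1,"p_value":0.8735,"deviance":14.73,"dof":22},{"species":"hake","design":"SMP_BL","L50":31.33,"L50_lo":15.02,"L50_hi":34.73,"SR":6.51,"SR_lo":0.1,"SR_hi":19.72,"C":0.38,"C_lo":0.27,"C_hi":1,"p_value":0.6995,"deviance":23.66,"dof":28},{"species":"hake","design":"CD_D","L50":15.68,"L50_lo":12.47,"L50_hi":17.51,"SR":7.92,"SR_lo":5.07,"SR_hi":11.84,"p_value":0.442,"deviance":36.57,"dof":36},{"species":"hake","design":"CD_S","L50":23.49,"L50_lo":22.82,"L50_hi":24.46,"SR":4.36,"SR_lo":3.73,"SR_hi":4.92,"p_value":0.8543,"deviance":25.46,"dof":34},{"species":"blue_whiting","design":"SMP_TS","L50":27.62,"L50_lo":23.14,"L50_hi":34.76,"SR":8.99,"SR_lo":0.1,"SR_hi":15.73,"C":0.27,"C_lo":0.21,"C_hi":0.38,"p_value":0.001,"deviance":105.1,"dof":40},{"species":"blue_whiting","design":"SMP_TL","L50":32.39,"L50_lo":29.81,"L50_hi":197.57,"SR":1.99,"SR_lo":0.1,"SR_hi":48.72,"C":0.45,"C_lo":0.26,"C_hi":0.66,"p_value":0.31,"deviance":25.81,"dof":23},{"species":"blue_whiting","design":"SMP_BS","L50":28.97,"L50_lo":0.1,"L50_hi":56.51,"SR":0.1,"SR_lo":0.1,"SR_hi":4.6,"C":0,"C_lo":0,"C_hi":1,"p_value":0.9793,"deviance":4.21,"dof":12},{"species":"blue_whiting","design":"SMP_BL","L50":0.1,"L50_lo":0.1,"L50_hi":1,"SR":27.73,"SR_lo":0.1,"SR_hi":40.5,"C":0.18,"C_lo":0.01,"C_hi":1,"p_value":0.6226,"deviance":8.99,"dof":11},{"species":"blue_whiting","design":"CD_D","L50":22.88,"L50_lo":20.76,"L50_hi":24.12,"SR":4.37,"SR_lo":3.6,"SR_hi":5.61,"p_value":0.1159,"deviance":21.7,"dof":15},{"species":"blue_whiting","design":"CD_S","L50":27.06,"L50_lo":26.7,"L50_hi":27.44,"SR":3.32,"SR_lo":2.85,"SR_hi":3.84,"p_value":0.3349,"deviance":19.96,"dof":18}]
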