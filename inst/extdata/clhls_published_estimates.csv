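age_group,stratum,quantity,earlier,later,diff,p
80-89,overall,total_le,6.38,6.58,0.20,0.044
80-89,overall,dfle,5.32,5.47,0.15,0.110
80-89,overall,disabled_le,1.06,1.10,0.04,0.740
80-89,men,total_le,6.14,6.22,0.08,0.566
80-89,men,dfle,5.29,5.28,-0.01,0.950
80-89,men,disabled_le,0.86,0.94,0.08,0.226
80-89,women,total_le,6.62,6.94,0.32,0.012
80-89,women,dfle,5.35,5.67,0.32,0.004
80-89,women,disabled_le,1.27,1.27,0.00,0.592
90-99,overall,total_le,3.96,3.94,-0.02,0.932
90-99,overall,dfle,2.47,2.88,0.41,<0.001
90-99,overall,disabled_le,1.49,1.06,-0.43,<0.001
90-99,men,total_le,3.83,3.71,-0.12,0.310
90-99,men,dfle,2.65,2.83,0.18,0.054
90-99,men,disabled_le,1.18,0.88,-0.30,<0.001
90-99,women,total_le,4.07,4.10,0.03,0.606
90-99,women,dfle,2.33,2.91,0.58,<0.001
90-99,women,disabled_le,1.74,1.19,-0.55,<0.001
100-105,overall,total_le,1.38,1.40,0.02,0.756
100-105,overall,dfle,0.65,0.72,0.07,0.050
100-105,overall,disabled_le,0.73,0.67,-0.06,0.088
100-105,men,total_le,1.30,1.32,0.02,0.744
100-105,men,dfle,0.76,0.75,-0.01,0.832
100-105,men,disabled_le,0.54,0.56,0.02,0.872
100-105,women,total_le,1.41,1.42,0.01,0.794
100-105,women,dfle,0.63,0.72,0.09,0.016
100-105,women,disabled_le,0.78,0.70,-0.08,0.052
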