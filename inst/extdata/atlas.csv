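region,side_rule,ap_min,ap_max,polygon
CA1_Py,mirror,-3.06,-0.90,-1700 0;-300 0;-300 260;-1700 260
CA1_Or,mirror,-3.06,-0.90,-1700 280;-300 280;-300 540;-1700 540
CA1_Rad,mirror,-3.06,-0.90,-1700 560;-300 560;-300 820;-1700 820
CA1_LMol,mirror,-3.06,-0.90,-1700 840;-300 840;-300 1100;-1700 1100
CA2_Py,mirror,-2.52,-1.26,-1700 1120;-300 1120;-300 1380;-1700 1380
CA2_Or,mirror,-2.52,-1.26,-1700 1400;-300 1400;-300 1660;-1700 1660
CA3_Py,mirror,-2.88,-0.90,-1700 1680;-300 1680;-300 1940;-1700 1940
CA3_Or,mirror,-2.88,-0.90,-1700 1960;-300 1960;-300 2220;-1700 2220
SUB,mirror,-3.87,-2.70,-1700 2240;-300 2240;-300 2500;-1700 2500
EC,mirror,-4.95,-2.70,-1700 2520;-300 2520;-300 2780;-1700 2780
OTHER,mirror,-4.95,1.08,-1700 2800;-300 2800;-300 3060;-1700 3060
MS_DB,midline,0.09,1.08,-140 0;140 0;140 260;-140 260
ReN,midline,-1.62,-0.36,-140 280;140 280;140 540;-140 540
MnR_PMnR,midline,-4.77,-3.96,-140 560;140 560;140 820;-140 820
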