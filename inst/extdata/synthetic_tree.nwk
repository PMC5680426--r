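((((((((t28:0.1907457016,t42:0.1907457016):0.4149400215,t7:0.6056857231):0.7513094672,t8:1.35699519):0.03735968078,((((t32:0.181985406,t44:0.181985406):0.3026485956,t31:0.4846340016):0.03140456157,(((t37:0.1125969521,t48:0.1125969521):0.1649792648,(t34:0.0970021009,t50:0.0970021009):0.180574116):0.1326075256,t4:0.4101837424):0.1058548208):0.4214373738,t15:0.937475937):0.4568789341):0.1191222484,((t6:0.2213877958,t40:0.2213877958):0.4500202495,t25:0.6714080452):0.8420690743):1.306408587,(((((t27:0.1106375009,t49:0.1106375009):0.5043867157,t14:0.6150242166):0.394934207,(t3:0.3280849304,t36:0.3280849304):0.6818734931):0.0998650196,(((t33:0.1227862614,t47:0.1227862614):0.3513779589,t18:0.4741642203):0.4018771817,t13:0.876041402):0.2337820412):0.1973255349,(t10:0.002305836359,t55:0.002305836359):1.304843142):1.512736729):0.1830057707,((((((((t20:0.681908298,t24:0.681908298):0.1167889088,(((t39:0.06386177793,t51:0.06386177793):0.1652036117,(t9:0.03019907281,t53:0.03019907281):0.1988663169):0.3582663641,t29:0.5873317538):0.211365453):0.01192471804,((t38:0.1247600214,t46:0.1247600214):0.1392094734,t19:0.2639694949):0.5466524299):0.07104587725,((t21:0.3336451367,t35:0.3336451367):0.4123037375,t17:0.7459488741):0.1357189279):0.3001327149,(t12:0.05647238745,t52:0.05647238745):1.125328129):0.05941188644,t11:1.241212403):0.08706477441,((t22:0.6226996737,t26:0.6226996737):0.1133885276,(t1:0.5614115374,t30:0.5614115374):0.1746766639):0.5921889764):0.7181002763,((((t45:0.01210757938,t54:0.01210757938):0.1172787211,t43:0.1293863005):0.05336222746,t23:0.182748528):0.5145135733,t5:0.6972621012):1.349115353):0.9565140234):1.619319893,((t2:0.1982308418,t41:0.1982308418):0.7265541162,t16:0.9247849579):3.697426413);
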