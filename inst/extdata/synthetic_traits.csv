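species,study,lc50_mg_l,duration_h,phylum,class,group
t1,synthetic,7789.341984085672,96,PhylumA,NA,NA
t2,synthetic,5211.07329119338,96,PhylumB,NA,macroinvertebrate
t3,synthetic,56025.3645351754,96,PhylumA,NA,NA
t4,synthetic,18981.008002593066,96,PhylumA,NA,NA
t5,synthetic,791.8186902770072,96,PhylumA,NA,NA
t6,synthetic,53730.60863558121,96,PhylumA,NA,NA
t7,synthetic,11645.364387183967,96,PhylumA,NA,NA
t8,synthetic,1535.3656844377977,96,PhylumA,NA,NA
t9,synthetic,41238.48994425777,96,PhylumA,NA,NA
t10,synthetic,1071848.0951822596,96,PhylumA,NA,NA
t11,synthetic,58551.71539641783,96,PhylumA,NA,NA
t12,synthetic,57620.60525862813,96,PhylumA,NA,NA
t13,synthetic,66713.72204582185,96,PhylumA,NA,NA
t14,synthetic,200334.27924329467,96,PhylumA,NA,NA
t15,synthetic,74917.86196160586,96,PhylumA,NA,NA
t16,synthetic,5089.879089210952,96,PhylumB,NA,macroinvertebrate
t17,synthetic,11368.630158998136,96,PhylumA,NA,NA
t18,synthetic,40027.599629003336,96,PhylumA,NA,NA
t19,synthetic,91532.02886125408,96,PhylumA,NA,NA
t20,synthetic,10701.001063047914,96,PhylumA,NA,NA
t21,synthetic,848.2661461490177,96,PhylumA,NA,NA
t22,synthetic,16152.159778174444,96,PhylumA,NA,NA
t23,synthetic,539.3914036091523,96,PhylumA,NA,NA
t24,synthetic,22465.08104551048,96,PhylumA,NA,NA
t25,synthetic,27266.247347093467,96,PhylumA,NA,NA
t26,synthetic,56380.26893172245,96,PhylumA,NA,NA
t27,synthetic,243678.3631017466,96,PhylumA,NA,NA
t28,synthetic,20041.309237796657,96,PhylumA,NA,NA
t29,synthetic,2240.7903108308933,96,PhylumA,NA,NA
t30,synthetic,14362.147807478448,96,PhylumA,NA,NA
t31,synthetic,54870.16443754327,96,PhylumA,NA,NA
t32,synthetic,15323.223684204444,96,PhylumA,NA,NA
t33,synthetic,12081.287229750214,96,PhylumA,NA,NA
t34,synthetic,8788.145223278827,96,PhylumA,NA,NA
t35,synthetic,1091.8838720727185,96,PhylumA,NA,NA
t36,synthetic,308730.13506643224,96,PhylumA,NA,NA
t37,synthetic,23192.719255322256,96,PhylumA,NA,NA
t38,synthetic,38446.50276517274,96,PhylumA,NA,NA
t39,synthetic,8065.972803764216,96,PhylumA,NA,NA
t40,synthetic,75246.2095044922,96,PhylumA,NA,NA
t41,synthetic,14635.689348883738,96,PhylumB,NA,macroinvertebrate
t42,synthetic,13731.446519918709,96,PhylumA,NA,NA
t43,synthetic,525.8501000707231,96,PhylumA,NA,NA
t44,synthetic,14431.908823386339,96,PhylumA,NA,NA
t45,synthetic,426.2783034075951,96,PhylumA,NA,NA
t46,synthetic,34774.04856194078,96,PhylumA,NA,NA
t47,synthetic,24408.667357589355,96,PhylumA,NA,NA
t48,synthetic,33897.74130543282,96,PhylumA,NA,NA
t49,synthetic,401691.2647149915,96,PhylumA,NA,NA
t50,synthetic,14182.831187089112,96,PhylumA,NA,NA
t51,synthetic,10131.533156696192,96,PhylumA,NA,NA
t52,synthetic,92940.04165130935,96,PhylumA,NA,NA
t53,synthetic,26773.87725684161,96,PhylumA,NA,NA
t54,synthetic,534.1125542529219,96,PhylumA,NA,NA
t55,synthetic,1064973.2971178389,96,PhylumA,NA,NA
t56_not_in_tree,synthetic,2500,48,PhylumB,NA,macroinvertebrate
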