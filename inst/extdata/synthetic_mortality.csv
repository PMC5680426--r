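pond_id,type,conc_mg_l,replicate,n_exposed,n_dead
roadside_1,roadside,0,1,10,0
roadside_1,roadside,0,2,10,0
roadside_1,roadside,0,3,10,0
roadside_1,roadside,0,4,10,0
roadside_1,roadside,3800,1,10,7
roadside_1,roadside,3800,2,10,7
roadside_1,roadside,3800,3,10,7
roadside_1,roadside,3800,4,10,8
roadside_1,roadside,5100,1,10,9
roadside_1,roadside,5100,2,10,10
roadside_1,roadside,5100,3,10,10
roadside_1,roadside,5100,4,10,10
roadside_1,roadside,6500,1,10,10
roadside_1,roadside,6500,2,10,10
roadside_1,roadside,6500,3,10,10
roadside_1,roadside,6500,4,10,10
roadside_1,roadside,7300,1,10,10
roadside_1,roadside,7300,2,10,10
roadside_1,roadside,7300,3,10,10
roadside_1,roadside,7300,4,10,10
roadside_2,roadside,0,1,10,0
roadside_2,roadside,0,2,10,0
roadside_2,roadside,0,3,10,0
roadside_2,roadside,0,4,10,0
roadside_2,roadside,3800,1,10,7
roadside_2,roadside,3800,2,10,8
roadside_2,roadside,3800,3,10,5
roadside_2,roadside,3800,4,10,6
roadside_2,roadside,5100,1,10,10
roadside_2,roadside,5100,2,10,9
roadside_2,roadside,5100,3,10,10
roadside_2,roadside,5100,4,10,10
roadside_2,roadside,6500,1,10,9
roadside_2,roadside,6500,2,10,10
roadside_2,roadside,6500,3,10,10
roadside_2,roadside,6500,4,10,10
roadside_2,roadside,7300,1,10,10
roadside_2,roadside,7300,2,10,10
roadside_2,roadside,7300,3,10,10
roadside_2,roadside,7300,4,10,10
roadside_3,roadside,0,1,10,0
roadside_3,roadside,0,2,10,0
roadside_3,roadside,0,3,10,0
roadside_3,roadside,0,4,10,0
roadside_3,roadside,3800,1,10,6
roadside_3,roadside,3800,2,10,5
roadside_3,roadside,3800,3,10,7
roadside_3,roadside,3800,4,10,5
roadside_3,roadside,5100,1,10,8
roadside_3,roadside,5100,2,10,10
roadside_3,roadside,5100,3,10,9
roadside_3,roadside,5100,4,10,10
roadside_3,roadside,6500,1,10,10
roadside_3,roadside,6500,2,10,10
roadside_3,roadside,6500,3,10,10
roadside_3,roadside,6500,4,10,10
roadside_3,roadside,7300,1,10,10
roadside_3,roadside,7300,2,10,10
roadside_3,roadside,7300,3,10,10
roadside_3,roadside,7300,4,10,10
roadside_4,roadside,0,1,10,0
roadside_4,roadside,0,2,10,0
roadside_4,roadside,0,3,10,0
roadside_4,roadside,0,4,10,0
roadside_4,roadside,3800,1,10,8
roadside_4,roadside,3800,2,10,8
roadside_4,roadside,3800,3,10,7
roadside_4,roadside,3800,4,10,4
roadside_4,roadside,5100,1,10,10
roadside_4,roadside,5100,2,10,8
roadside_4,roadside,5100,3,10,8
roadside_4,roadside,5100,4,10,9
roadside_4,roadside,6500,1,10,10
roadside_4,roadside,6500,2,10,10
roadside_4,roadside,6500,3,10,10
roadside_4,roadside,6500,4,10,10
roadside_4,roadside,7300,1,10,10
roadside_4,roadside,7300,2,10,10
roadside_4,roadside,7300,3,10,10
roadside_4,roadside,7300,4,10,10
roadside_5,roadside,0,1,10,0
roadside_5,roadside,0,2,10,0
roadside_5,roadside,0,3,10,0
roadside_5,roadside,0,4,10,0
roadside_5,roadside,3800,1,10,6
roadside_5,roadside,3800,2,10,6
roadside_5,roadside,3800,3,10,7
roadside_5,roadside,3800,4,10,3
roadside_5,roadside,5100,1,10,7
roadside_5,roadside,5100,2,10,10
roadside_5,roadside,5100,3,10,10
roadside_5,roadside,5100,4,10,10
roadside_5,roadside,6500,1,10,10
roadside_5,roadside,6500,2,10,10
roadside_5,roadside,6500,3,10,10
roadside_5,roadside,6500,4,10,10
roadside_5,roadside,7300,1,10,10
roadside_5,roadside,7300,2,10,10
roadside_5,roadside,7300,3,10,10
roadside_5,roadside,7300,4,10,10
woodland_1,woodland,0,1,10,0
woodland_1,woodland,0,2,10,0
woodland_1,woodland,0,3,10,0
woodland_1,woodland,0,4,10,0
woodland_1,woodland,3800,1,10,3
woodland_1,woodland,3800,2,10,8
woodland_1,woodland,3800,3,10,3
woodland_1,woodland,3800,4,10,4
woodland_1,woodland,5100,1,10,9
woodland_1,woodland,5100,2,10,8
woodland_1,woodland,5100,3,10,7
woodland_1,woodland,5100,4,10,9
woodland_1,woodland,6500,1,10,9
woodland_1,woodland,6500,2,10,10
woodland_1,woodland,6500,3,10,10
woodland_1,woodland,6500,4,10,10
woodland_1,woodland,7300,1,10,10
woodland_1,woodland,7300,2,10,10
woodland_1,woodland,7300,3,10,10
woodland_1,woodland,7300,4,10,10
woodland_2,woodland,0,1,10,0
woodland_2,woodland,0,2,10,0
woodland_2,woodland,0,3,10,0
woodland_2,woodland,0,4,10,0
woodland_2,woodland,3800,1,10,2
woodland_2,woodland,3800,2,10,2
woodland_2,woodland,3800,3,10,6
woodland_2,woodland,3800,4,10,4
woodland_2,woodland,5100,1,10,8
woodland_2,woodland,5100,2,10,7
woodland_2,woodland,5100,3,10,7
woodland_2,woodland,5100,4,10,5
woodland_2,woodland,6500,1,10,10
woodland_2,woodland,6500,2,10,10
woodland_2,woodland,6500,3,10,10
woodland_2,woodland,6500,4,10,9
woodland_2,woodland,7300,1,10,10
woodland_2,woodland,7300,2,10,10
woodland_2,woodland,7300,3,10,10
woodland_2,woodland,7300,4,10,10
woodland_3,woodland,0,1,10,0
woodland_3,woodland,0,2,10,0
woodland_3,woodland,0,3,10,0
woodland_3,woodland,0,4,10,0
woodland_3,woodland,3800,1,10,4
woodland_3,woodland,3800,2,10,3
woodland_3,woodland,3800,3,10,4
woodland_3,woodland,3800,4,10,3
woodland_3,woodland,5100,1,10,8
woodland_3,woodland,5100,2,10,6
woodland_3,woodland,5100,3,10,7
woodland_3,woodland,5100,4,10,8
woodland_3,woodland,6500,1,10,9
woodland_3,woodland,6500,2,10,10
woodland_3,woodland,6500,3,10,10
woodland_3,woodland,6500,4,10,9
woodland_3,woodland,7300,1,10,10
woodland_3,woodland,7300,2,10,10
woodland_3,woodland,7300,3,10,10
woodland_3,woodland,7300,4,10,10
woodland_4,woodland,0,1,10,0
woodland_4,woodland,0,2,10,0
woodland_4,woodland,0,3,10,0
woodland_4,woodland,0,4,10,0
woodland_4,woodland,3800,1,10,3
woodland_4,woodland,3800,2,10,4
woodland_4,woodland,3800,3,10,3
woodland_4,woodland,3800,4,10,2
woodland_4,woodland,5100,1,10,4
woodland_4,woodland,5100,2,10,7
woodland_4,woodland,5100,3,10,2
woodland_4,woodland,5100,4,10,3
woodland_4,woodland,6500,1,10,9
woodland_4,woodland,6500,2,10,10
woodland_4,woodland,6500,3,10,10
woodland_4,woodland,6500,4,10,10
woodland_4,woodland,7300,1,10,10
woodland_4,woodland,7300,2,10,10
woodland_4,woodland,7300,3,10,10
woodland_4,woodland,7300,4,10,10
woodland_5,woodland,0,1,10,0
woodland_5,woodland,0,2,10,0
woodland_5,woodland,0,3,10,0
woodland_5,woodland,0,4,10,0
woodland_5,woodland,3800,1,10,2
woodland_5,woodland,3800,2,10,6
woodland_5,woodland,3800,3,10,2
woodland_5,woodland,3800,4,10,6
woodland_5,woodland,5100,1,10,8
woodland_5,woodland,5100,2,10,9
woodland_5,woodland,5100,3,10,4
woodland_5,woodland,5100,4,10,8
woodland_5,woodland,6500,1,10,10
woodland_5,woodland,6500,2,10,10
woodland_5,woodland,6500,3,10,10
woodland_5,woodland,6500,4,10,10
woodland_5,woodland,7300,1,10,9
woodland_5,woodland,7300,2,10,10
woodland_5,woodland,7300,3,10,10
woodland_5,woodland,7300,4,10,10
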