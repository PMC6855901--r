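metabolite_id,sub_pathway,is_differential,log2_fc,ga_slope,decay_rate,lod_threshold
M0001,pathway_03,TRUE,-4.862971400092567,0,0.04139684512279927,5214.517363631361
M0002,pathway_04,TRUE,-2.557607919789154,0,0,24830.563216591992
M0003,pathway_01,TRUE,-4.029783550597381,0,0,528.2221238890306
M0004,pathway_04,FALSE,0,0,0,24675.29052019862
M0005,pathway_03,FALSE,0,0,0,1070298.941422071
M0006,pathway_01,FALSE,0,0,0.07072417230345308,79799.57915552355
M0007,pathway_04,TRUE,-3.8688891691469207,0,0,101.66412561983478
M0008,pathway_04,FALSE,0,0,0,501.2168277704234
M0009,pathway_01,FALSE,0,0,0,7584.019181149401
M0010,pathway_02,TRUE,-2.2473632274059803,0,0,1861.1526240858757
M0011,pathway_01,FALSE,0,0,0,120078.65768882864
M0012,pathway_01,FALSE,0,0,0,133133.42940318453
M0013,pathway_02,TRUE,2.7641763024108257,0,0,469.53909072215737
M0014,pathway_04,TRUE,-3.6144731476730656,0.14338242267258466,0,19971.38567924359
M0015,pathway_02,FALSE,0,0,0,2369.678909333563
M0016,pathway_02,TRUE,-1.6997510757814296,-0.058763285074383026,0,2944.451971501697
M0017,pathway_02,FALSE,0,0,0.06511170162819326,2153.12956969915
M0018,pathway_01,TRUE,2.5775471200564017,-0.14397702999413015,0,2969.09790661821
M0019,pathway_04,FALSE,0,0,0,3625.821356923011
M0020,pathway_03,FALSE,0,0,0,193406.40754691412
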