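"metabolite_id","REF001","REF002","REF003","REF004","REF005","REF006"
"M0001","433644.73129646649","283782.79277076299","301675.46850363683","428621.95977207192","88908.896425674597","354575.70204165165"
"M0002","228820.89537845881","298423.81661511422","201634.93341713972","256925.37622102795","201503.56863610301","214816.00130784098"
"M0003","7447.8835396937957","4449.073986870163","3763.6419514025397","5755.9456876476488","6535.5123073009572","12115.322036611702"
"M0004","62929.149957391783","39094.555229283062","36827.771018215062","42483.016875975612","26879.309266578275","44711.206681005038"
"M0005",,,,,,"1380790.0894545505"
"M0006","913119.84973493498","397622.80400625902","619113.83740287274","544083.19551007345",,"319191.47843540902"
"M0007","2211.3187499251521","2263.2019881685319","2395.2179378656206","1897.3538713064552","1101.7450886773361","4084.6377864153501"
"M0008","3465.4015680204543","1658.2054869591902","2695.9752722797484","1229.9983557413916","1548.818839013418","2813.4808987538349"
"M0009","10780.984080598557",,"9221.9137133627155","8477.7377915552515","9856.3462570129996","13012.101679279476"
"M0010","18442.673987659076","23538.0160802235","7837.7329373445309","11871.878157710071","5022.2927427352515","19959.507763265348"
"M0011","140101.07241648267","134177.64755110099","176411.84937936498","219903.68140967126","147916.06511597044","249263.8086670769"
"M0012","187623.77835295597",,,"217185.17100879038","193612.93274400671","187461.96157949851"
"M0013","1967.8252361633238","1275.133737141251","587.01887756611688","666.64255751883047","605.48200487288011","2507.2101301181692"
"M0014","237561.4333100704","133241.76477821081","233667.87947162858","134925.07278160899","195436.2984843115","173488.03443271606"
"M0015","4893.2362118771434","7747.0742814320183",,"5211.2645177325248","3695.9827599529717","6952.7833504645041"
"M0016","27005.246898071022","39050.670256589568","7910.8477795570989","39156.167075520585","38532.001544426683","17598.77429550287"
"M0017","13421.229118864907","14059.903714455129","6409.0979574138928","7953.137236221226",,"2922.6242472353592"
"M0018",,,,,"3047.1676871744526",
"M0019","9302.427827330328","4589.2661893074555","5172.7599042364009","6904.6080843071013","4048.0831097687701","9270.6727710321284"
"M0020","242899.18175855346","252605.08825716045","211770.47606474697","477294.08342484827","252527.73974071763","352900.93879865512"
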