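"metabolite_id","P001","P002","P003","P004","P005","P006","P007","N001","N002","N003","N004","N005"
"M0001",,"5272.4048950441102","5295.5543738760998",,"12360.745484167581","16077.160863761166","7966.5955794604715","409158.95575034741","128875.37177590549","405287.20074006123","680376.49717466114","88397.25875483932"
"M0002","33135.023592334037","27018.451137054744",,"31195.13961515791",,"32792.404670750409","29340.716048621434","160035.52488401599","127699.36918248198","88848.877642721025","136296.56813902647","145418.14859449153"
"M0003","626.54307053325317",,,"821.64511326746697","760.65589237652978","1153.2128979266813","860.26545288791749","3974.1610805243349","10252.795737569111","15121.608584580054","16353.388489997633","19774.386710061666"
"M0004","54469.929976348518","52265.663921893953","32282.979741631574","30514.024154960589","41131.541103218588","45044.150129333619","24931.19627287229","63408.88028886653",,"33252.150006180149",,"30100.60182977232"
"M0005","1960679.8617816472","1089698.1128471014","1078490.8966037098",,"1975186.1363196634","1330504.1704339259","2112382.9955500136","1353907.9518679476","1799173.3095434257","1482485.7979535188",,"1318744.3299732264"
"M0006",,"669102.69341015094","695517.19262042223","621287.18559920613","649792.72172879183","566314.84742556757","179527.62236550383","714467.08908876113",,"674645.13427829114","985235.96605898777","90003.104656611627"
"M0007","226.72029489997217","426.17631421463932",,,"162.81577669466321","404.52239291360064","255.41278145354755","1816.3048513740234","266.22575802428412","890.43345215049544","872.70343567832435","1414.8099293033674"
"M0008","2789.8355405327147","3663.5605527192433","681.8617770353668","1984.6507606828086",,"8964.29827321833","1024.7248308785952","1932.1470100117858",,"713.33023858396587","1174.0978645076502","1301.516725993813"
"M0009","10861.737493887889",,"10406.72195332242","13122.247765292368","10355.145607938082","17541.463743356257","15330.471758526986",,"10031.560786561244","10417.028934624848","10824.185701673101","12829.742321213342"
"M0010","8121.2626783671303",,"2157.1556259234831","6209.1714086117381","7214.2552339232743","3906.995932212611",,"19487.470801779982","19271.337650499299","13719.245422797199","17754.486365594232","13905.034292134422"
"M0011","233633.03891129108",,"127921.19315995392","195025.33312247775","293495.22232247854","279520.32433787006","264252.8501330163",,"170277.1761404289","238020.62143257473","187468.94919800136","134988.66495134428"
"M0012","403375.01163762511",,"162054.02618061798","313067.32706568605","326976.33266434353","300979.53864380438","298299.85574969935",,"371256.5566401222","311455.48415093089","401272.08391610283","476845.47344302858"
"M0013","24057.22610872706","2567.0980701854851","3956.4406676549597","4703.9465983352338","10464.739219618064","4778.5947304564525","5161.6112086949788","2235.3342789434414",,,"673.24962290251096","713.40134411607198"
"M0014",,"26164.769069275917",,"31785.717919339404","20246.6370874737","22401.019419755052","22918.397676493416","127038.8470889134","101669.42790136978","97455.904446462053","115930.25915073643","176255.09404370282"
"M0015","12037.871684902233",,"3210.1375608919452","5819.0005614166976","7667.9485455968988","3020.8563882584767","4546.7130185578226","5553.9373483943064","3449.6585955310043",,"3749.3697791557374","6631.2247780430034"
"M0016","12272.270577143194",,"11765.349370316588",,"7080.7028057957086","5044.9411635755941","3033.5454787155641","28207.014932408521","25092.822637367306","29979.911319065337","21178.837123885613","24787.769327168975"
"M0017","2652.1260605079146","2756.6623354056992","3726.2356953790281","8666.3564802801484","4750.269412255414","5605.5571886462822",,"9013.0587536124785",,"2542.1226132499801","8727.8799035405737","2547.9440963813272"
"M0018","10618.309489050649","3087.2738075427355","4961.5031948857659","11089.839822950145","5568.374816977579","9863.4216285297589","17672.221590526111","5058.5291015136054",,,"6883.0706132426922","3211.9210491603571"
"M0019","25329.004695180487","9979.3507302445068",,"7985.7795071074397","4525.0570238675327","18832.179218375728","5508.2694289819556","4416.8151501770044",,"6121.4359259159946","6389.6785005963575","9071.8180683677419"
"M0020","446258.61456917151","330534.38453643973","234825.44378355154",,"408756.36125530192","283870.72497259983","292329.9628063697","244334.55477207835","384477.13631498785","330822.68764426047","302576.11467454385",
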