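id,lon,lat,households,price,city_id
a01,1000,1000,250,18000,alpha
a02,1400,900,520,17500,alpha
a03,2100,1800,130,16000,alpha
a04,3000,2500,800,21000,alpha
a05,5200,4100,310,12500,alpha
a06,6800,900,95,9800,alpha
a07,900,6400,410,11000,alpha
a08,4400,4600,620,19500,alpha
b01,1200,1500,300,8200,beta
b02,2500,2200,150,7600,beta
b03,6100,5800,720,9100,beta
b04,6500,6200,90,8800,beta
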