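site,state,latitude_deg,longitude_w_deg,elevation_m,mat_c,map_mm,lai,use
Caspar Creek,CA,39.3726,123.7063,240,10.8,1175.4,3.5,validation
Coweeta,NC,35.0467,83.4574,910,12.2,2259.2,5.5,calibration
Duke,NC,33.9760,79.0924,170,15.8,1434.8,2.5,validation
Fraser,CO,39.9296,105.8698,2710,2.9,576.4,2.5,validation
Marcell,MN,47.5057,93.4861,430,3.7,670.6,2.2,calibration
San Dimas,CA,34.2064,117.7615,670,17.7,523.1,0.1,calibration
Santee,SC,33.1482,79.7910,8,18.6,1673.9,2.5,calibration
Sierra Ancha,AZ,33.8039,110.9159,2220,11.2,717.8,2.2,validation
Tenderfoot Creek,MT,46.9236,110.8697,2130,2.2,857.8,2.2,validation
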