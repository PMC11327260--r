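label,common_name,binomial,subfamily,family,specimen_id,tooth_position,locality
PlainsZebra,Plains zebra,Equus quagga,Equinae,Equidae,NMBF 382,P2 lower right,Unknown
WhiteRhinoceros,Southern white rhinoceros,Ceratotherium simum,Rhinocerotinae,Rhinocerotidae,NMBF 624,P1 upper left,Zululand
Giraffe,Giraffe,Giraffa camelopardalis,Giraffinae,Giraffidae,NMBF 6062,P3 upper right,Unknown
Hippopotamus,Hippopotamus,Hippopotamus amphibius,Hippopotaminae,Hippopotamidae,NMBF 335,P2 upper right,Unknown
Waterbuck,Waterbuck,Kobus ellipsiprymnus,Reduncinae,Bovidae,NMBF 8893,P1 lower right,Kruger National Park
Reedbuck,Southern reedbuck,Redunca arundinum,Reduncinae,Bovidae,NMBF 8905,M3 lower left,Unknown
Impala,Impala,Aepyceros melampus,Aepycerotinae,Bovidae,NMBF 8814,P1 lower left,Unknown
GreaterKudu,Greater kudu,Tragelaphus strepsiceros,Bovinae,Bovidae,NMBF 236,P1 upper right,Unknown
Eland,Common eland,Taurotragus oryx,Bovinae,Bovidae,NMBF 8756,M1 upper left,Bloemfontein Zoo
Springbok,Springbok,Antidorcas marsupialis,Antilopinae,Bovidae,NMBF 103,P2 upper left,Unknown
Steenbok,Steenbok,Raphicerus campestris,Antilopinae,Bovidae,NMBF 9343,M1 upper left,Bultfontein Road
BlackWildebeest,Black wildebeest,Connochaetes gnou,Alcelaphinae,Bovidae,NMBF 8707,M3 upper right,Willem Pretorius Game Reserve
BlueWildebeest,Blue wildebeest,Connochaetes taurinus,Alcelaphinae,Bovidae,NMBF 52,M3 upper right,Unknown
Hartebeest,Hartebeest,Alcelaphus buselaphus,Alcelaphinae,Bovidae,NMBF 12421,M2 lower right,Soetdoring Nature Reserve
Blesbok,Blesbok,Damaliscus pygargus,Alcelaphinae,Bovidae,NMBF 9384,P1 upper left,"Erfenisdam, Theunissen"
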