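code,species,ocean,fao_area,specimen,level,fragment
YFT,Thunnus albacares,AO,FAO 34,1,L1,AB
YFT,Thunnus albacares,AO,FAO 34,1,L2,AB
YFT,Thunnus albacares,AO,FAO 34,1,L3,AB
YFT,Thunnus albacares,AO,FAO 34,1,L4O,B
YFT,Thunnus albacares,AO,FAO 34,1,L4B,B
YFT,Thunnus albacares,AO,FAO 34,2,L1,AB
YFT,Thunnus albacares,AO,FAO 34,2,L2,AB
YFT,Thunnus albacares,AO,FAO 34,2,L3,AB
YFT,Thunnus albacares,AO,FAO 34,2,L4O,B
YFT,Thunnus albacares,AO,FAO 34,2,L4B,B
YFT,Thunnus albacares,AO,FAO 34,3,L1,AB
YFT,Thunnus albacares,AO,FAO 34,3,L2,AB
YFT,Thunnus albacares,AO,FAO 34,3,L3,na
YFT,Thunnus albacares,AO,FAO 34,3,L4O,B
YFT,Thunnus albacares,AO,FAO 34,3,L4B,B
YFT,Thunnus albacares,IO,FAO 51,1,L1,AB
YFT,Thunnus albacares,IO,FAO 51,1,L2,AB
YFT,Thunnus albacares,IO,FAO 51,1,L3,AB
YFT,Thunnus albacares,IO,FAO 51,1,L4O,B
YFT,Thunnus albacares,IO,FAO 51,1,L4B,B
YFT,Thunnus albacares,IO,FAO 51,2,L1,AB
YFT,Thunnus albacares,IO,FAO 51,2,L2,AB
YFT,Thunnus albacares,IO,FAO 51,2,L3,AB
YFT,Thunnus albacares,IO,FAO 51,2,L4O,B
YFT,Thunnus albacares,IO,FAO 51,2,L4B,B
YFT,Thunnus albacares,IO,FAO 51,3,L1,AB
YFT,Thunnus albacares,IO,FAO 51,3,L2,AB
YFT,Thunnus albacares,IO,FAO 51,3,L3,AB
YFT,Thunnus albacares,IO,FAO 51,3,L4O,B
YFT,Thunnus albacares,IO,FAO 51,3,L4B,B
YFT,Thunnus albacares,EPO,FAO 87,1,L1,AB
YFT,Thunnus albacares,EPO,FAO 87,1,L2,AB
YFT,Thunnus albacares,EPO,FAO 87,1,L3,AB
YFT,Thunnus albacares,EPO,FAO 87,1,L4O,B
YFT,Thunnus albacares,EPO,FAO 87,1,L4B,B
YFT,Thunnus albacares,EPO,FAO 87,2,L1,AB
YFT,Thunnus albacares,EPO,FAO 87,2,L2,AB
YFT,Thunnus albacares,EPO,FAO 87,2,L3,AB
YFT,Thunnus albacares,EPO,FAO 87,2,L4O,B
YFT,Thunnus albacares,EPO,FAO 87,2,L4B,B
YFT,Thunnus albacares,EPO,FAO 87,3,L1,AB
YFT,Thunnus albacares,EPO,FAO 87,3,L2,AB
YFT,Thunnus albacares,EPO,FAO 87,3,L3,AB
YFT,Thunnus albacares,EPO,FAO 87,3,L4O,B
YFT,Thunnus albacares,EPO,FAO 87,3,L4B,B
YFT,Thunnus albacares,WCPO,FAO 71,1,L1,AB
YFT,Thunnus albacares,WCPO,FAO 71,1,L2,AB
YFT,Thunnus albacares,WCPO,FAO 71,1,L3,AB
YFT,Thunnus albacares,WCPO,FAO 71,1,L4O,B
YFT,Thunnus albacares,WCPO,FAO 71,1,L4B,B
YFT,Thunnus albacares,WCPO,FAO 71,2,L1,AB
YFT,Thunnus albacares,WCPO,FAO 71,2,L2,AB
YFT,Thunnus albacares,WCPO,FAO 71,2,L3,AB
YFT,Thunnus albacares,WCPO,FAO 71,2,L4O,B
YFT,Thunnus albacares,WCPO,FAO 71,2,L4B,B
YFT,Thunnus albacares,WCPO,FAO 71,3,L1,AB
YFT,Thunnus albacares,WCPO,FAO 71,3,L2,AB
YFT,Thunnus albacares,WCPO,FAO 71,3,L3,AB
YFT,Thunnus albacares,WCPO,FAO 71,3,L4O,B
YFT,Thunnus albacares,WCPO,FAO 71,3,L4B,B
BET,Thunnus obesus,IO,FAO 51,1,L1,AB
BET,Thunnus obesus,IO,FAO 51,1,L2,AB
BET,Thunnus obesus,IO,FAO 51,1,L3,A
BET,Thunnus obesus,IO,FAO 51,1,L4O,B
BET,Thunnus obesus,IO,FAO 51,1,L4B,B
BET,Thunnus obesus,IO,FAO 51,2,L1,AB
BET,Thunnus obesus,IO,FAO 51,2,L2,AB
BET,Thunnus obesus,IO,FAO 51,2,L3,A
BET,Thunnus obesus,IO,FAO 51,2,L4O,B
BET,Thunnus obesus,IO,FAO 51,2,L4B,B
BET,Thunnus obesus,IO,FAO 51,3,L1,AB
BET,Thunnus obesus,IO,FAO 51,3,L2,AB
BET,Thunnus obesus,IO,FAO 51,3,L3,A
BET,Thunnus obesus,IO,FAO 51,3,L4O,B
BET,Thunnus obesus,IO,FAO 51,3,L4B,B
BET,Thunnus obesus,EPO,FAO 87,1,L1,AB
BET,Thunnus obesus,EPO,FAO 87,1,L2,AB
BET,Thunnus obesus,EPO,FAO 87,1,L3,A
BET,Thunnus obesus,EPO,FAO 87,1,L4O,B
BET,Thunnus obesus,EPO,FAO 87,1,L4B,B
BET,Thunnus obesus,EPO,FAO 87,2,L1,AB
BET,Thunnus obesus,EPO,FAO 87,2,L2,AB
BET,Thunnus obesus,EPO,FAO 87,2,L3,A
BET,Thunnus obesus,EPO,FAO 87,2,L4O,B
BET,Thunnus obesus,EPO,FAO 87,2,L4B,B
BET,Thunnus obesus,EPO,FAO 87,3,L1,AB
BET,Thunnus obesus,EPO,FAO 87,3,L2,AB
BET,Thunnus obesus,EPO,FAO 87,3,L3,A
BET,Thunnus obesus,EPO,FAO 87,3,L4O,B
BET,Thunnus obesus,EPO,FAO 87,3,L4B,B
LOT,Thunnus tonggol,IO,FAO 51,1,L1,AB
LOT,Thunnus tonggol,IO,FAO 51,1,L2,AB
LOT,Thunnus tonggol,IO,FAO 51,1,L3,A
LOT,Thunnus tonggol,IO,FAO 51,1,L4O,B
LOT,Thunnus tonggol,IO,FAO 51,1,L4B,B
LOT,Thunnus tonggol,IO,FAO 51,2,L1,AB
LOT,Thunnus tonggol,IO,FAO 51,2,L2,AB
LOT,Thunnus tonggol,IO,FAO 51,2,L3,AB
LOT,Thunnus tonggol,IO,FAO 51,2,L4O,B
LOT,Thunnus tonggol,IO,FAO 51,2,L4B,B
LOT,Thunnus tonggol,IO,FAO 51,3,L1,AB
LOT,Thunnus tonggol,IO,FAO 51,3,L2,AB
LOT,Thunnus tonggol,IO,FAO 51,3,L3,AB
LOT,Thunnus tonggol,IO,FAO 51,3,L4O,B
LOT,Thunnus tonggol,IO,FAO 51,3,L4B,B
SKJ,Katsuwonus pelamis,AO,FAO 34,1,L1,AB
SKJ,Katsuwonus pelamis,AO,FAO 34,1,L2,AB
SKJ,Katsuwonus pelamis,AO,FAO 34,1,L3,AB
SKJ,Katsuwonus pelamis,AO,FAO 34,1,L4O,A
SKJ,Katsuwonus pelamis,AO,FAO 34,1,L4B,B
SKJ,Katsuwonus pelamis,AO,FAO 34,2,L1,AB
SKJ,Katsuwonus pelamis,AO,FAO 34,2,L2,AB
SKJ,Katsuwonus pelamis,AO,FAO 34,2,L3,AB
SKJ,Katsuwonus pelamis,AO,FAO 34,2,L4O,B
SKJ,Katsuwonus pelamis,AO,FAO 34,2,L4B,B
SKJ,Katsuwonus pelamis,AO,FAO 34,3,L1,AB
SKJ,Katsuwonus pelamis,AO,FAO 34,3,L2,AB
SKJ,Katsuwonus pelamis,AO,FAO 34,3,L3,na
SKJ,Katsuwonus pelamis,AO,FAO 34,3,L4O,B
SKJ,Katsuwonus pelamis,AO,FAO 34,3,L4B,B
SKJ,Katsuwonus pelamis,IO,FAO 51,1,L1,AB
SKJ,Katsuwonus pelamis,IO,FAO 51,1,L2,AB
SKJ,Katsuwonus pelamis,IO,FAO 51,1,L3,AB
SKJ,Katsuwonus pelamis,IO,FAO 51,1,L4O,B
SKJ,Katsuwonus pelamis,IO,FAO 51,1,L4B,B
SKJ,Katsuwonus pelamis,IO,FAO 51,2,L1,AB
SKJ,Katsuwonus pelamis,IO,FAO 51,2,L2,AB
SKJ,Katsuwonus pelamis,IO,FAO 51,2,L3,AB
SKJ,Katsuwonus pelamis,IO,FAO 51,2,L4O,B
SKJ,Katsuwonus pelamis,IO,FAO 51,2,L4B,na
SKJ,Katsuwonus pelamis,IO,FAO 51,3,L1,AB
SKJ,Katsuwonus pelamis,IO,FAO 51,3,L2,AB
SKJ,Katsuwonus pelamis,IO,FAO 51,3,L3,AB
SKJ,Katsuwonus pelamis,IO,FAO 51,3,L4O,B
SKJ,Katsuwonus pelamis,IO,FAO 51,3,L4B,B
SKJ,Katsuwonus pelamis,EPO,FAO 87,1,L1,AB
SKJ,Katsuwonus pelamis,EPO,FAO 87,1,L2,AB
SKJ,Katsuwonus pelamis,EPO,FAO 87,1,L3,AB
SKJ,Katsuwonus pelamis,EPO,FAO 87,1,L4O,B
SKJ,Katsuwonus pelamis,EPO,FAO 87,1,L4B,B
SKJ,Katsuwonus pelamis,EPO,FAO 87,2,L1,AB
SKJ,Katsuwonus pelamis,EPO,FAO 87,2,L2,AB
SKJ,Katsuwonus pelamis,EPO,FAO 87,2,L3,AB
SKJ,Katsuwonus pelamis,EPO,FAO 87,2,L4O,B
SKJ,Katsuwonus pelamis,EPO,FAO 87,2,L4B,B
SKJ,Katsuwonus pelamis,EPO,FAO 87,3,L1,AB
SKJ,Katsuwonus pelamis,EPO,FAO 87,3,L2,AB
SKJ,Katsuwonus pelamis,EPO,FAO 87,3,L3,AB
SKJ,Katsuwonus pelamis,EPO,FAO 87,3,L4O,B
SKJ,Katsuwonus pelamis,EPO,FAO 87,3,L4B,B
SKJ,Katsuwonus pelamis,WCPO,FAO 71,1,L1,AB
SKJ,Katsuwonus pelamis,WCPO,FAO 71,1,L2,AB
SKJ,Katsuwonus pelamis,WCPO,FAO 71,1,L3,AB
SKJ,Katsuwonus pelamis,WCPO,FAO 71,1,L4O,B
SKJ,Katsuwonus pelamis,WCPO,FAO 71,1,L4B,B
SKJ,Katsuwonus pelamis,WCPO,FAO 71,2,L1,AB
SKJ,Katsuwonus pelamis,WCPO,FAO 71,2,L2,AB
SKJ,Katsuwonus pelamis,WCPO,FAO 71,2,L3,AB
SKJ,Katsuwonus pelamis,WCPO,FAO 71,2,L4O,B
SKJ,Katsuwonus pelamis,WCPO,FAO 71,2,L4B,B
SKJ,Katsuwonus pelamis,WCPO,FAO 71,3,L1,AB
SKJ,Katsuwonus pelamis,WCPO,FAO 71,3,L2,AB
SKJ,Katsuwonus pelamis,WCPO,FAO 71,3,L3,AB
SKJ,Katsuwonus pelamis,WCPO,FAO 71,3,L4O,B
SKJ,Katsuwonus pelamis,WCPO,FAO 71,3,L4B,B
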