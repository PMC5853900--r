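label,name,vertex,mat,map
TrRF,tropical rainforest,1,20,2500
TrRF,tropical rainforest,2,32,2500
TrRF,tropical rainforest,3,32,5000
TrRF,tropical rainforest,4,20,5000
TSF,tropical seasonal forest,1,20,1300
TSF,tropical seasonal forest,2,32,1300
TSF,tropical seasonal forest,3,32,2500
TSF,tropical seasonal forest,4,20,2500
S,savanna,1,20,250
S,savanna,2,32,250
S,savanna,3,32,1300
S,savanna,4,20,1300
TeRF,temperate rainforest,1,3,2300
TeRF,temperate rainforest,2,20,2300
TeRF,temperate rainforest,3,20,5000
TeRF,temperate rainforest,4,3,5000
TF,temperate forest,1,3,700
TF,temperate forest,2,20,700
TF,temperate forest,3,20,2300
TF,temperate forest,4,3,2300
WGS,woodland/grassland/shrubland,1,3,250
WGS,woodland/grassland/shrubland,2,20,250
WGS,woodland/grassland/shrubland,3,20,700
WGS,woodland/grassland/shrubland,4,3,700
D,desert,1,3,0
D,desert,2,32,0
D,desert,3,32,250
D,desert,4,3,250
Ta,taiga,1,-5,0
Ta,taiga,2,3,0
Ta,taiga,3,3,5000
Ta,taiga,4,-5,5000
Tu,tundra,1,-25,0
Tu,tundra,2,-5,0
Tu,tundra,3,-5,5000
Tu,tundra,4,-25,5000
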