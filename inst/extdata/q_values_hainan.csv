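code,variable,q,rank
X1,temperature,0.088,11
X2,precipitation,0.420,8
X3,elevation,0.195,10
X4,slope,0.208,9
X5,aspect,0.018,12
X6,land_use,0.595,1
X7,vegetation_type,0.488,4
X8,ndvi,0.577,2
X9,soil_erosion,0.429,7
X10,soil_type,0.483,5
X11,population,0.461,6
X12,gdp,0.492,3
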