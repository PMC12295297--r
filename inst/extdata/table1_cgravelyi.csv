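species,parameter,unit,n,mean,sd,min,max
Ceratosolen gravelyi,eye height,um,20,147.6,5.9,137.8,164.7
Ceratosolen gravelyi,eye width,um,20,201.3,6.0,188.0,210.5
Ceratosolen gravelyi,facet number,count,11,247,14,228,263
Ceratosolen gravelyi,eye radius,um,3,90.4,5.9,86.4,97.4
Ceratosolen gravelyi,facet diameter,um,150,11.8,0.7,9.3,13.7
Ceratosolen gravelyi,ommatidium length,um,30,54.3,6.8,46.8,59.9
Ceratosolen gravelyi,interommatidial angle,deg,30,9.3,0.9,7.7,12.5
Ceratosolen gravelyi,outer lens radius,um,20,7.1,0.6,5.6,8.3
Ceratosolen gravelyi,inner lens radius,um,20,8.7,0.9,7.7,10.8
Ceratosolen gravelyi,corneal thickness,um,50,5.7,0.8,4.1,7.9
Ceratosolen gravelyi,chitin layer number,count,20,9.0,1.0,8,10
Ceratosolen gravelyi,cone length,um,50,12.7,2.3,9.3,18.4
Ceratosolen gravelyi,cone distal diameter,um,50,8.9,1.2,6.4,11.3
Ceratosolen gravelyi,ppc pigment granule diameter,um,150,0.62,0.11,0.4,1.0
Ceratosolen gravelyi,spc pigment granule diameter,um,150,0.57,0.12,0.3,0.8
Ceratosolen gravelyi,rhabdom length,um,20,35.7,4.3,29.1,43.9
Ceratosolen gravelyi,rhabdom distal diameter,um,20,2.4,0.2,2.0,2.8
Ceratosolen gravelyi,rhabdom proximal diameter,um,12,0.69,0.1,0.5,0.9
Ceratosolen gravelyi,microvillus diameter,nm,150,57.2,7.5,41.1,81.6
Ceratosolen gravelyi,retinular pigment granule diameter,um,150,0.47,0.10,0.2,0.7
Ceratosolen gravelyi,hair number,count,20,15,2,13,19
Ceratosolen gravelyi,hair length,um,30,13.0,3.9,6.5,21.6
Ceratosolen gravelyi,hair basal diameter,um,30,1.4,0.2,1.0,1.7
Ceratosolen gravelyi,basal matrix thickness,nm,20,198.9,63.3,128,354
Ceratosolen gravelyi,median ocellus diameter,um,15,35.0,,25.5,42.8
Ceratosolen gravelyi,lateral ocellus diameter,um,15,33.2,,25.5,42.8
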