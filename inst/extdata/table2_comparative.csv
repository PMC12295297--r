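species,parameter,unit,value,value_min,value_max
Ceratosolen gravelyi,body_size_mm,mm,2.74,,
Ceratosolen gravelyi,P1,1/um,0.064,,
Ceratosolen gravelyi,P2,1/um,0.012,,
Ceratosolen gravelyi,P3,1/um,-0.003,,
Ceratosolen gravelyi,P_total,1/um,0.073,,
Ceratosolen gravelyi,f_um,um,13.7,,
Ceratosolen gravelyi,f_image_um,um,18.5,,
Ceratosolen gravelyi,F_number,,1.1,,
Ceratosolen gravelyi,acceptance_angle_deg,deg,10.0,,
Ceratosolen gravelyi,airy_halfwidth_deg,deg,2.4,,
Ceratosolen gravelyi,sensitivity_um2_sr,um^2/sr,0.26,,
Ceratosolen gravelyi,facet_diameter_um,um,11.8,,
Megaphragma mymaripenne,body_size_mm,mm,0.2,,
Megaphragma mymaripenne,P1,1/um,0.133,,
Megaphragma mymaripenne,P2,1/um,0.037,,
Megaphragma mymaripenne,P3,1/um,-0.009,,
Megaphragma mymaripenne,P_total,1/um,0.161,,
Megaphragma mymaripenne,f_um,um,6.2,,
Megaphragma mymaripenne,f_image_um,um,8.4,,
Megaphragma mymaripenne,F_number,,0.8,,
Megaphragma mymaripenne,acceptance_angle_deg,deg,22.2,,
Megaphragma mymaripenne,airy_halfwidth_deg,deg,3.5,,
Megaphragma mymaripenne,sensitivity_um2_sr,um^2/sr,0.23,,
Megaphragma mymaripenne,facet_diameter_um,um,8.1,,
Trichogramma evanescens,body_size_mm,mm,,0.3,0.4
Trichogramma evanescens,P1,1/um,0.098,,
Trichogramma evanescens,P2,1/um,0.016,,
Trichogramma evanescens,P3,1/um,-0.002,,
Trichogramma evanescens,P_total,1/um,0.112,,
Trichogramma evanescens,f_um,um,8.9,,
Trichogramma evanescens,f_image_um,um,12.0,,
Trichogramma evanescens,F_number,,1.4,,
Trichogramma evanescens,acceptance_angle_deg,deg,8.1,,
Trichogramma evanescens,airy_halfwidth_deg,deg,4.5,,
Trichogramma evanescens,sensitivity_um2_sr,um^2/sr,0.06,,
Trichogramma evanescens,facet_diameter_um,um,6.39,,
Anaphes flavipes,body_size_mm,mm,0.45,,
Anaphes flavipes,P1,1/um,0.076,,
Anaphes flavipes,P2,1/um,0.021,,
Anaphes flavipes,P3,1/um,-0.004,,
Anaphes flavipes,P_total,1/um,0.094,,
Anaphes flavipes,f_um,um,10.7,,
Anaphes flavipes,f_image_um,um,14.4,,
Anaphes flavipes,F_number,,1.3,,
Anaphes flavipes,acceptance_angle_deg,deg,4.8,,
Anaphes flavipes,airy_halfwidth_deg,deg,3.5,,
Anaphes flavipes,sensitivity_um2_sr,um^2/sr,0.04,,
Anaphes flavipes,facet_diameter_um,um,8.1,,
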