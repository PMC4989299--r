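view,feature,all_mean,symptomatic_mean,asymptomatic_mean
longitudinal,thickness_cm,0.56,0.68,0.52
longitudinal,echogenicity,82.37,79.32,83.48
longitudinal,variance,618.72,654.93,605.50
longitudinal,skewness,0.52,0.65,0.47
longitudinal,kurtosis,3.82,4.18,3.68
longitudinal,entropy,6.50,6.51,6.50
longitudinal,contrast,0.64,0.61,0.65
longitudinal,energy,0.21,0.21,0.21
longitudinal,homogeneity,0.76,0.77,0.76
transverse,area_cm2,0.61,0.76,0.56
transverse,thickness_cm,0.57,0.67,0.53
transverse,width_cm,1.32,1.37,1.30
transverse,echogenicity,90.98,86.62,92.57
transverse,variance,767.57,789.63,759.51
transverse,skewness,0.54,0.63,0.51
transverse,kurtosis,3.61,3.78,3.55
transverse,entropy,6.74,6.73,6.74
transverse,contrast,0.90,0.84,0.92
transverse,energy,0.14,0.15,0.14
transverse,homogeneity,0.73,0.74,0.73
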