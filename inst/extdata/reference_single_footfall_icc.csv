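category,subphase,pace,icc21
duration_pct,ICP,comfortable,0.79
duration_pct,LCP,comfortable,0.46
duration_pct,FFP,comfortable,0.42
duration_pct,CbP,comfortable,0.76
duration_pct,IPP,comfortable,0.62
duration_pct,LPP,comfortable,0.55
stance_duration_ms,,comfortable,0.87
timepoint_pct,MON,comfortable,0.79
timepoint_pct,FFT,comfortable,0.47
timepoint_pct,HOT,comfortable,0.77
timepoint_pct,MOF,comfortable,0.55
range_ml_mm,ICP,comfortable,0.13
range_ml_mm,LCP,comfortable,0.49
range_ml_mm,FFP,comfortable,0.23
range_ml_mm,CbP,comfortable,0.46
range_ml_mm,IPP,comfortable,0.51
range_ml_mm,LPP,comfortable,0.39
range_ap_mm,ICP,comfortable,0.46
range_ap_mm,LCP,comfortable,0.48
range_ap_mm,FFP,comfortable,0.41
range_ap_mm,CbP,comfortable,0.78
range_ap_mm,IPP,comfortable,0.71
range_ap_mm,LPP,comfortable,0.60
vel_ml_cms,ICP,comfortable,0.22
vel_ml_cms,LCP,comfortable,0.45
vel_ml_cms,FFP,comfortable,0.25
vel_ml_cms,CbP,comfortable,0.52
vel_ml_cms,IPP,comfortable,0.26
vel_ml_cms,LPP,comfortable,0.32
vel_ap_cms,ICP,comfortable,0.43
vel_ap_cms,LCP,comfortable,0.63
vel_ap_cms,FFP,comfortable,0.50
vel_ap_cms,CbP,comfortable,0.72
vel_ap_cms,IPP,comfortable,0.63
vel_ap_cms,LPP,comfortable,0.40
vel_tot_cms,ICP,comfortable,0.46
vel_tot_cms,LCP,comfortable,0.62
vel_tot_cms,FFP,comfortable,0.50
vel_tot_cms,CbP,comfortable,0.71
vel_tot_cms,IPP,comfortable,0.55
vel_tot_cms,LPP,comfortable,0.36
mloc_ml_pct,ICP,comfortable,0.40
mloc_ml_pct,LCP,comfortable,0.46
mloc_ml_pct,FFP,comfortable,0.37
mloc_ml_pct,CbP,comfortable,0.43
mloc_ml_pct,IPP,comfortable,0.45
mloc_ml_pct,LPP,comfortable,0.50
mloc_ap_pct,ICP,comfortable,0.40
mloc_ap_pct,LCP,comfortable,0.47
mloc_ap_pct,FFP,comfortable,0.54
mloc_ap_pct,CbP,comfortable,0.52
mloc_ap_pct,IPP,comfortable,0.72
mloc_ap_pct,LPP,comfortable,0.74
duration_pct,ICP,fast,0.74
duration_pct,LCP,fast,0.44
duration_pct,FFP,fast,0.40
duration_pct,CbP,fast,0.75
duration_pct,IPP,fast,0.48
duration_pct,LPP,fast,0.55
stance_duration_ms,,fast,0.88
timepoint_pct,MON,fast,0.74
timepoint_pct,FFT,fast,0.45
timepoint_pct,HOT,fast,0.76
timepoint_pct,MOF,fast,0.55
range_ml_mm,ICP,fast,0.17
range_ml_mm,LCP,fast,0.46
range_ml_mm,FFP,fast,0.22
range_ml_mm,CbP,fast,0.48
range_ml_mm,IPP,fast,0.49
range_ml_mm,LPP,fast,0.42
range_ap_mm,ICP,fast,0.53
range_ap_mm,LCP,fast,0.49
range_ap_mm,FFP,fast,0.34
range_ap_mm,CbP,fast,0.73
range_ap_mm,IPP,fast,0.69
range_ap_mm,LPP,fast,0.59
vel_ml_cms,ICP,fast,0.25
vel_ml_cms,LCP,fast,0.47
vel_ml_cms,FFP,fast,0.24
vel_ml_cms,CbP,fast,0.51
vel_ml_cms,IPP,fast,0.38
vel_ml_cms,LPP,fast,0.34
vel_ap_cms,ICP,fast,0.51
vel_ap_cms,LCP,fast,0.59
vel_ap_cms,FFP,fast,0.55
vel_ap_cms,CbP,fast,0.71
vel_ap_cms,IPP,fast,0.63
vel_ap_cms,LPP,fast,0.45
vel_tot_cms,ICP,fast,0.51
vel_tot_cms,LCP,fast,0.58
vel_tot_cms,FFP,fast,0.55
vel_tot_cms,CbP,fast,0.70
vel_tot_cms,IPP,fast,0.56
vel_tot_cms,LPP,fast,0.41
mloc_ml_pct,ICP,fast,0.36
mloc_ml_pct,LCP,fast,0.49
mloc_ml_pct,FFP,fast,0.41
mloc_ml_pct,CbP,fast,0.50
mloc_ml_pct,IPP,fast,0.40
mloc_ml_pct,LPP,fast,0.41
mloc_ap_pct,ICP,fast,0.36
mloc_ap_pct,LCP,fast,0.45
mloc_ap_pct,FFP,fast,0.48
mloc_ap_pct,CbP,fast,0.54
mloc_ap_pct,IPP,fast,0.70
mloc_ap_pct,LPP,fast,0.72
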