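table,block_param,block_value,n,method,relbias_bI_pct,relbias_se_bI_pct,coverage_wald_pct,coverage_pl_pct,power_wald_pct,power_pl_pct,N_c
marker_effect,HR_M,0.6,200,mple,46.5,45.7,96.6,96.6,2.5,5.0,4912
marker_effect,HR_M,0.6,400,mple,16.4,31.0,96.8,96.9,12.6,23.1,7671
marker_effect,HR_M,0.6,600,mple,1.6,21.2,97.2,97.3,33.0,46.0,8895
marker_effect,HR_M,0.6,200,firth,19.0,37.3,97.6,96.7,2.4,11.3,9703
marker_effect,HR_M,0.6,400,firth,5.2,21.1,96.9,96.8,12.2,29.3,9995
marker_effect,HR_M,0.6,600,firth,0.5,12.3,97.0,96.6,31.6,46.6,10000
marker_effect,HR_M,1,200,mple,23.9,30.0,96.6,96.7,8.5,15.2,6950
marker_effect,HR_M,1,400,mple,0,16.8,97.2,97.1,35.6,46.3,9129
marker_effect,HR_M,1,600,mple,-5.7,6.5,96.8,96.0,61.6,68.1,9750
marker_effect,HR_M,1,200,firth,8.6,24.8,97.2,96.6,7.5,21.5,9969
marker_effect,HR_M,1,400,firth,0.8,9.9,97.0,96.1,33.7,46.5,9999
marker_effect,HR_M,1,600,firth,-0.5,4.2,96.5,95.3,59.3,65.8,10000
marker_effect,HR_M,3,200,mple,-4.2,4.8,96.4,95.6,44.7,50.2,9724
marker_effect,HR_M,3,400,mple,-3.7,-2.1,95.5,94.7,79.4,81.0,9991
marker_effect,HR_M,3,600,mple,-3.2,-0.4,95.7,95.1,93.8,94.3,10000
marker_effect,HR_M,3,200,firth,0.7,5.2,96.6,95.1,41.5,48.8,10000
marker_effect,HR_M,3,400,firth,0.4,0.9,95.7,94.9,77.5,80.0,10000
marker_effect,HR_M,3,600,firth,-0.5,2.2,96.1,95.5,93.3,94.0,10000
marker_prevalence,p_M,0.25,200,mple,33.8,15.0,97.2,96.6,1.8,3.2,8692
marker_prevalence,p_M,0.25,400,mple,-15.7,2.3,96.8,95.3,3.8,6.6,9855
marker_prevalence,p_M,0.25,600,mple,-18.4,-2.0,95.9,94.6,6.2,8.8,9978
marker_prevalence,p_M,0.25,200,firth,11.2,12.2,97.6,96.0,1.4,4.2,9946
marker_prevalence,p_M,0.25,400,firth,3.4,3.3,97.0,95.5,3.1,6.0,9999
marker_prevalence,p_M,0.25,600,firth,-0.8,0.7,96.3,95.1,5.0,7.4,10000
marker_prevalence,p_M,0.5,200,mple,-20.3,-1.7,95.9,94.7,4.9,7.1,9900
marker_prevalence,p_M,0.5,400,mple,-11.9,-3.1,95.0,94.5,7.9,9.2,9999
marker_prevalence,p_M,0.5,600,mple,-8.2,-2.0,94.9,94.5,10.2,11.1,10000
marker_prevalence,p_M,0.5,200,firth,2.9,3.6,96.8,95.1,3.5,6.0,9998
marker_prevalence,p_M,0.5,400,firth,1.7,0.5,95.7,94.7,6.3,7.9,10000
marker_prevalence,p_M,0.5,600,firth,0.5,0.3,95.3,94.9,8.7,10.1,10000
marker_prevalence,p_M,0.75,200,mple,0.6,6.6,97.2,96.2,2.7,4.6,9477
marker_prevalence,p_M,0.75,400,mple,-8.2,-0.5,95.7,95.0,5.9,7.6,9911
marker_prevalence,p_M,0.75,600,mple,-9.6,-1.8,95.4,94.9,8.8,10.1,9984
marker_prevalence,p_M,0.75,200,firth,20.7,10.9,97.6,96.3,2.1,4.0,9792
marker_prevalence,p_M,0.75,400,firth,6.7,3.0,96.3,95.3,4.9,6.6,9947
marker_prevalence,p_M,0.75,600,firth,1.1,0.9,95.9,95.2,7.5,9.1,9988
treatment_marker_or,OR_MT,0.5,200,mple,-10.7,1.1,96.4,95.3,10.9,15.2,9792
treatment_marker_or,OR_MT,0.5,400,mple,-7.2,-2.6,95.2,94.3,23.8,26.7,9994
treatment_marker_or,OR_MT,0.5,600,mple,-5.2,-2.5,94.9,94.4,34.6,36.9,10000
treatment_marker_or,OR_MT,0.5,200,firth,1.0,4.2,96.9,95.3,8.1,13.4,10000
treatment_marker_or,OR_MT,0.5,400,firth,0.9,0.8,95.7,94.8,20.3,24.1,10000
treatment_marker_or,OR_MT,0.5,600,firth,0.1,0.1,95.6,94.8,31.6,34.5,10000
treatment_marker_or,OR_MT,1,200,mple,-7.4,-0.4,96.6,95.1,13.0,16.0,9907
treatment_marker_or,OR_MT,1,400,mple,-4.2,-2.5,95.4,94.6,25.9,27.4,9999
treatment_marker_or,OR_MT,1,600,mple,-2.7,-1.0,95.1,94.7,36.9,37.9,10000
treatment_marker_or,OR_MT,1,200,firth,-1.0,4.5,97.3,95.5,10.6,14.8,9998
treatment_marker_or,OR_MT,1,400,firth,-0.1,1.0,96.0,95.2,24.0,26.3,9999
treatment_marker_or,OR_MT,1,600,firth,-0.1,1.2,95.6,95.1,35.2,37.0,10000
treatment_marker_or,OR_MT,2,200,mple,-0.5,-0.5,96.3,95.1,13.2,14.6,9901
treatment_marker_or,OR_MT,2,400,mple,-0.4,-2.1,95.4,94.9,26.2,26.5,9979
treatment_marker_or,OR_MT,2,600,mple,-0.5,-0.7,95.2,94.9,36.6,36.7,9990
treatment_marker_or,OR_MT,2,200,firth,-0.6,5.4,97.2,95.7,11.8,14.7,9954
treatment_marker_or,OR_MT,2,400,firth,-0.1,1.3,96.1,95.2,25.6,27.0,9980
treatment_marker_or,OR_MT,2,600,firth,-0.3,1.5,95.8,95.2,36.2,37.3,9990
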