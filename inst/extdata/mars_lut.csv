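code,name,region,source,threshold,dilate
1,brainstem,infratentorial,harvard_oxford_subcortical,50,FALSE
2,cerebellum,infratentorial,mni_structural,NA,FALSE
3,basal_ganglia,deep,harvard_oxford_subcortical,50,FALSE
4,thalamus,deep,harvard_oxford_subcortical,50,FALSE
5,internal_capsule,deep,jhu_icbm_dti81,NA,FALSE
6,external_capsule,deep,jhu_icbm_dti81,NA,FALSE
7,corpus_callosum,deep,jhu_icbm_dti81,NA,FALSE
8,deep_white_matter,deep,harvard_oxford_subcortical,60,FALSE
9,frontal,lobar,mni_structural,NA,TRUE
10,parietal,lobar,mni_structural,NA,TRUE
11,temporal,lobar,mni_structural,NA,TRUE
12,occipital,lobar,mni_structural,NA,TRUE
13,insula,lobar,mni_structural,NA,TRUE
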