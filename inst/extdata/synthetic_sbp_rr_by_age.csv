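disease,age_group,rr_per_10mmhg,rr_lo,rr_hi,source
ihd,15-19,2.655,2.182,3.23,synthetic_gbd_style
ihd,20-24,2.492,2.048,3.032,synthetic_gbd_style
ihd,25-29,2.339,1.923,2.845,synthetic_gbd_style
ihd,30-34,2.196,1.805,2.671,synthetic_gbd_style
ihd,35-39,2.061,1.694,2.507,synthetic_gbd_style
ihd,40-44,1.935,1.591,2.354,synthetic_gbd_style
ihd,45-49,1.816,1.493,2.209,synthetic_gbd_style
ihd,50-54,1.705,1.402,2.074,synthetic_gbd_style
ihd,55-59,1.6,1.315,1.946,synthetic_gbd_style
ihd,60-64,1.502,1.235,1.827,synthetic_gbd_style
ihd,65-69,1.41,1.159,1.715,synthetic_gbd_style
ihd,70-74,1.323,1.088,1.609,synthetic_gbd_style
ihd,75-79,1.242,1.021,1.511,synthetic_gbd_style
ihd,80-84,1.166,0.958,1.418,synthetic_gbd_style
ihd,85-89,1.094,0.899,1.331,synthetic_gbd_style
ihd,90-94,1.05,0.863,1.277,synthetic_gbd_style
ihd,95-99,1.05,0.863,1.277,synthetic_gbd_style
ihd,100-104,1.05,0.863,1.277,synthetic_gbd_style
isch_stroke,15-19,2.944,2.42,3.581,synthetic_gbd_style
isch_stroke,20-24,2.758,2.267,3.355,synthetic_gbd_style
isch_stroke,25-29,2.585,2.125,3.145,synthetic_gbd_style
isch_stroke,30-34,2.422,1.991,2.946,synthetic_gbd_style
isch_stroke,35-39,2.27,1.866,2.762,synthetic_gbd_style
isch_stroke,40-44,2.127,1.748,2.588,synthetic_gbd_style
isch_stroke,45-49,1.993,1.638,2.425,synthetic_gbd_style
isch_stroke,50-54,1.868,1.536,2.272,synthetic_gbd_style
isch_stroke,55-59,1.75,1.439,2.129,synthetic_gbd_style
isch_stroke,60-64,1.64,1.348,1.995,synthetic_gbd_style
isch_stroke,65-69,1.537,1.263,1.87,synthetic_gbd_style
isch_stroke,70-74,1.44,1.184,1.752,synthetic_gbd_style
isch_stroke,75-79,1.349,1.109,1.641,synthetic_gbd_style
isch_stroke,80-84,1.264,1.039,1.538,synthetic_gbd_style
isch_stroke,85-89,1.185,0.974,1.442,synthetic_gbd_style
isch_stroke,90-94,1.11,0.912,1.35,synthetic_gbd_style
isch_stroke,95-99,1.05,0.863,1.277,synthetic_gbd_style
isch_stroke,100-104,1.05,0.863,1.277,synthetic_gbd_style
haem_stroke,15-19,3.414,2.806,4.153,synthetic_gbd_style
haem_stroke,20-24,3.183,2.616,3.872,synthetic_gbd_style
haem_stroke,25-29,2.968,2.44,3.611,synthetic_gbd_style
haem_stroke,30-34,2.767,2.275,3.366,synthetic_gbd_style
haem_stroke,35-39,2.58,2.121,3.139,synthetic_gbd_style
haem_stroke,40-44,2.406,1.978,2.927,synthetic_gbd_style
haem_stroke,45-49,2.243,1.844,2.729,synthetic_gbd_style
haem_stroke,50-54,2.091,1.719,2.544,synthetic_gbd_style
haem_stroke,55-59,1.95,1.603,2.372,synthetic_gbd_style
haem_stroke,60-64,1.818,1.494,2.212,synthetic_gbd_style
haem_stroke,65-69,1.695,1.393,2.062,synthetic_gbd_style
haem_stroke,70-74,1.581,1.3,1.923,synthetic_gbd_style
haem_stroke,75-79,1.474,1.212,1.793,synthetic_gbd_style
haem_stroke,80-84,1.374,1.129,1.672,synthetic_gbd_style
haem_stroke,85-89,1.281,1.053,1.558,synthetic_gbd_style
haem_stroke,90-94,1.195,0.982,1.454,synthetic_gbd_style
haem_stroke,95-99,1.114,0.916,1.355,synthetic_gbd_style
haem_stroke,100-104,1.05,0.863,1.277,synthetic_gbd_style
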