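sex,site,icd10,outcome,beta,rr_avg,rr_ci_low,rr_ci_high
male,oral_cavity,C00-C09,incidence,0.015,1.53,0.77,2.96
male,pharynx,C10-C14,incidence,0.024,1.98,1.62,2.42
male,esophagus,C15,incidence,0.004,1.12,1.00,1.26
male,colon,C18,incidence,0.004,1.12,0.80,1.53
male,rectum,C20,incidence,0.004,1.12,0.80,1.53
male,liver,C22,incidence,0.002,1.06,1.03,1.09
male,larynx,C32,incidence,0.013,1.45,0.82,2.56
female,oral_cavity,C00-C09,incidence,0.015,1.10,0.94,1.27
female,pharynx,C10-C14,incidence,0.024,1.17,1.11,1.22
female,esophagus,C15,incidence,0.004,1.03,1.00,1.05
female,colon,C18,incidence,0.027,1.19,0.88,1.60
female,rectum,C20,incidence,0.027,1.19,0.88,1.60
female,liver,C22,incidence,0.002,1.01,1.01,1.02
female,larynx,C32,incidence,0.013,1.09,0.96,1.23
female,breast,C50,incidence,0.001,1.01,0.99,1.02
male,oral_cavity,C00-C09,mortality,0.012,1.41,1.22,1.67
male,pharynx,C10-C14,mortality,0.012,1.41,1.22,1.67
male,esophagus,C15,mortality,0.010,1.33,1.12,1.62
male,colon,C18,mortality,0.002,1.06,0.94,1.19
male,rectum,C20,mortality,0.002,1.06,0.94,1.19
male,liver,C22,mortality,0.003,1.09,1.06,1.15
male,larynx,C32,mortality,0.009,1.29,1.09,1.49
female,oral_cavity,C00-C09,mortality,0.012,1.08,1.05,1.12
female,pharynx,C10-C14,mortality,0.012,1.08,1.05,1.12
female,esophagus,C15,mortality,0.010,1.07,1.03,1.11
female,colon,C18,mortality,0.002,1.01,0.99,1.04
female,rectum,C20,mortality,0.002,1.01,0.99,1.04
female,liver,C22,mortality,0.003,1.02,1.01,1.03
female,larynx,C32,mortality,0.009,1.06,1.02,1.09
female,breast,C50,mortality,0.001,1.01,0.99,1.02
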