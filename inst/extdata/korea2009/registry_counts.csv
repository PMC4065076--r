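sex,site,outcome,count,year,all_cancers_count
male,oral_cavity,incidence,1128,2009,96826
male,pharynx,incidence,703,2009,96826
male,esophagus,incidence,1947,2009,96826
male,colon,incidence,7886,2009,96826
male,rectum,incidence,7063,2009,96826
male,liver,incidence,11663,2009,96826
male,larynx,incidence,1071,2009,96826
male,oral_cavity,mortality,397,2009,43658
male,pharynx,mortality,368,2009,43658
male,esophagus,mortality,1297,2009,43658
male,colon,mortality,2206,2009,43658
male,rectum,mortality,1722,2009,43658
male,liver,mortality,8422,2009,43658
male,larynx,mortality,382,2009,43658
female,oral_cavity,incidence,512,2009,91068
female,pharynx,incidence,114,2009,91068
female,esophagus,incidence,175,2009,91068
female,colon,incidence,4643,2009,91068
female,rectum,incidence,3458,2009,91068
female,liver,incidence,3539,2009,91068
female,larynx,incidence,56,2009,91068
female,breast,incidence,11536,2009,91068
female,oral_cavity,mortality,153,2009,25773
female,pharynx,mortality,55,2009,25773
female,esophagus,mortality,109,2009,25773
female,colon,mortality,1978,2009,25773
female,rectum,mortality,1142,2009,25773
female,liver,mortality,2814,2009,25773
female,larynx,mortality,1878,2009,25773
female,breast,mortality,395,2009,25773
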