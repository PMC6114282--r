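param,term,estimate,estimate_date,se,df,t,p
departure_date,Intercept,,2016-12-08,4.77,6,8950.755,<0.001
departure_date,Front (STF),-11.3,,5.34,6,-2.121,0.078
departure_date,Sex (Male),-0.7,,5.34,6,-0.128,0.903
max_range_km,Intercept,2190.2,,93.47,6,23.433,<0.001
max_range_km,Front (STF),-745.4,,104.49,6,-7.133,<0.001
max_range_km,Sex (Male),82.4,,104.49,6,0.788,0.461
daily_km_median,Intercept,74.9,,4.29,6,17.459,<0.001
daily_km_median,Front (STF),-11.9,,4.80,6,-2.488,0.047
daily_km_median,Sex (Male),-1.6,,4.80,6,-0.326,0.756
duration_days,Intercept,69.1,,4.59,2,15.066,0.004
duration_days,Front (STF),-0.4,,6.49,2,-0.066,0.953
duration_days,Sex (Male),2.6,,6.49,2,0.396,0.730
trip_length_km,Intercept,6156.7,,478.54,2,12.866,0.006
trip_length_km,Front (STF),-1823.1,,676.75,2,-2.703,0.114
trip_length_km,Sex (Male),-691.1,,676.75,2,-1.021,0.415
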