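subject_id,age,sex,family_history_dm,bmi,waist,fpg,hba1c,fasting_insulin,homa_ir,triglycerides,hdl,sbp,dbp,antihypertensive_use,tar_propensity_pct,outcome_t2d_5y,wear_days
S0001,37.2,male,TRUE,33.4,97.7,83.6,5.35,28.73,5.93,105.9,43.9,120.9,81.6,FALSE,2.821,FALSE,5
S0002,41.5,female,TRUE,38.8,83.6,104.1,5.75,5.04,1.3,115.3,42.1,111.6,76.8,FALSE,37.04,FALSE,4
S0003,40.7,female,FALSE,34.8,78.9,96.5,5.42,14.25,3.39,111.7,62,111.5,59.4,FALSE,0.357,FALSE,5
S0004,42.4,male,TRUE,33.6,102.4,85.6,5.33,12.74,2.69,111.6,47.3,133,67.8,TRUE,1.93,FALSE,5
S0005,35.3,male,FALSE,29.7,101.4,95.8,5.73,5.35,1.27,97.9,52.9,122.3,78.7,FALSE,39.243,FALSE,5
S0006,19.2,female,FALSE,34.2,88.8,104.3,5.68,9.06,2.33,174.4,67.7,123.2,78.7,FALSE,8.326,FALSE,5
S0007,35.5,female,TRUE,25.8,99.5,84.2,4.94,20.64,4.29,213.3,60.3,124.8,83.5,FALSE,0.89,FALSE,5
S0008,46.1,female,FALSE,36.1,81.9,92,5.8,8.77,1.99,75.4,52.7,120.4,73.9,FALSE,9.711,FALSE,5
S0009,49.5,female,TRUE,32.6,79.1,78.2,5.15,12.21,2.36,41.2,64.1,122.1,71.7,FALSE,0.598,FALSE,5
S0010,72.5,female,FALSE,28.3,86.6,66.5,5.09,12.33,2.02,95,53.8,119.9,66.5,FALSE,0.257,FALSE,5
S0011,56,male,FALSE,28.1,98,75,5.31,6.85,1.27,130.1,58.7,130.7,77.4,FALSE,0.206,FALSE,5
S0012,35.1,female,TRUE,27.3,83,84.7,5.28,19.2,4.01,105.6,68.6,121.6,74.8,FALSE,3.032,FALSE,5
S0013,35,female,TRUE,26,78.6,90,5.19,4.3,0.96,54.9,60.5,133.7,92.2,FALSE,0.639,FALSE,5
S0014,46.3,male,TRUE,25.7,107.1,69.4,5.05,9.66,1.66,64.7,47.4,127.8,80.9,FALSE,0.12,FALSE,5
S0015,34.3,female,FALSE,29.7,80.9,96.6,5.45,16.89,4.03,208,56.4,127.9,77.6,FALSE,3.277,FALSE,5
S0016,64,female,TRUE,18,80.8,82.1,5.05,12.06,2.44,85.3,62.6,116.2,76.4,FALSE,0.047,FALSE,5
S0017,38.2,female,FALSE,37.3,103.3,99.5,5.45,5.15,1.26,99,62.6,123.7,74.9,FALSE,12.449,FALSE,5
S0018,67.2,male,TRUE,37.7,112.9,126.3,7,27.25,8.5,164.8,67.4,134,80.4,FALSE,64.878,TRUE,5
S0019,43.1,female,TRUE,33.6,75.3,80.2,5.07,29.54,5.85,136.5,52.3,126.3,73.6,TRUE,0.307,FALSE,3
S0020,53.3,female,FALSE,24.3,99.4,89,5.44,19.95,4.39,44.3,69.2,115.2,75.8,FALSE,1.786,FALSE,5
S0021,61.6,female,FALSE,35.1,92.1,114,6.97,11.45,3.23,158.2,66.3,139.5,62.1,TRUE,28.173,TRUE,5
S0022,38.2,female,TRUE,27,82.6,80.9,5.4,9.36,1.87,125.8,58.9,119.3,73.6,FALSE,0.511,FALSE,6
S0023,21.7,female,FALSE,25.2,87.6,83.8,5.56,6.71,1.39,120.7,55.4,132.3,69.3,TRUE,2.413,FALSE,5
S0024,30.2,female,FALSE,29.1,90.6,82.2,5.39,15.34,3.11,262.1,63.1,124.3,81.5,TRUE,0.703,FALSE,4
S0025,52.2,female,TRUE,35.9,89.1,102,5.41,10.49,2.64,143.9,46.9,113.4,72.4,FALSE,2.953,FALSE,5
S0026,46,female,TRUE,25,72.4,101.9,5.6,3.46,0.87,114.5,69.6,140.7,76.4,TRUE,0.235,FALSE,5
S0027,26.6,female,TRUE,33,89.4,86.5,5.57,28.08,6,65.6,49.4,126.6,77.6,FALSE,36.82,FALSE,5
S0028,39,male,TRUE,27.2,110.3,89.5,5.65,6.64,1.47,138,48,130.6,88.4,FALSE,8.114,FALSE,3
S0029,79.8,female,FALSE,34.1,88,77.8,5.09,20.44,3.92,50.5,39.3,109.6,70.5,FALSE,0.183,FALSE,5
S0030,26.8,female,TRUE,37.2,77.9,92,5.55,6.81,1.55,75.9,59.3,117.3,72.1,FALSE,28.11,FALSE,5
S0031,40,male,TRUE,23.2,92.3,91.1,5.09,13.29,2.99,102.7,37.2,124.2,66.3,TRUE,0.276,FALSE,5
S0032,64.6,female,TRUE,32,84.8,80.1,4.73,14.77,2.92,117.5,42.6,125.8,76.2,FALSE,0.029,FALSE,5
S0033,47.2,male,FALSE,21.6,110,71.7,5.06,23.55,4.17,143,51.1,101.3,83.7,FALSE,0.022,FALSE,5
S0034,46.7,male,FALSE,30.6,104.6,80.4,5.39,11.28,2.24,135.3,49.3,127,79.7,FALSE,0.594,FALSE,3
S0035,41.6,female,FALSE,25.5,78.7,86.1,5.17,4.1,0.87,190.3,64.2,108.2,72.6,FALSE,2.23,FALSE,5
S0036,65.1,female,TRUE,42.1,95.9,137.3,7.29,34.1,11.56,119.3,47.1,144,80.2,FALSE,78.456,TRUE,5
S0037,34.2,female,TRUE,17.6,80.6,89.5,5.34,21.21,4.68,112.3,59,119.7,78,FALSE,5.274,FALSE,5
S0038,77.5,female,TRUE,29.5,84.1,96.2,5.5,3.73,0.89,123.8,58.1,115.1,72.4,FALSE,5.853,FALSE,5
S0039,55.9,female,TRUE,33.9,92.6,92.6,5.73,7.89,1.8,86.3,59.5,138.9,85.2,FALSE,1.343,FALSE,5
S0040,35.9,male,FALSE,19.6,104.9,111.9,5.94,10.38,2.87,84.9,50.6,118.1,80.3,FALSE,57.213,FALSE,5
S0041,47.9,female,TRUE,27.4,86.9,103,5.47,1.56,0.4,134.2,51.8,131.6,94.9,FALSE,2.302,FALSE,5
S0042,52.5,female,TRUE,34.2,101.9,113,5.3,32.06,8.95,82.4,70.4,141.2,62.7,TRUE,2.217,TRUE,5
S0043,63.6,male,FALSE,36.6,105.3,88.2,5.46,14.91,3.25,52.3,26.6,111.3,80.5,FALSE,0.047,FALSE,5
S0044,51.6,female,TRUE,18.8,80.6,90.1,5.04,6.49,1.44,110,83.4,107.3,71.2,FALSE,1.798,FALSE,5
S0045,40.7,female,FALSE,27.4,79.8,77.3,5.16,12.66,2.42,238.3,81.5,110.4,77.4,FALSE,3.264,FALSE,5
S0046,60.9,female,TRUE,28,89.8,76.9,5.42,10.68,2.03,62.4,61.7,135.3,65.8,FALSE,4.827,FALSE,5
S0047,64.4,female,FALSE,32.9,74.5,90,4.92,44.91,9.98,60.6,71.2,135.3,84,FALSE,0.053,FALSE,5
S0048,31.3,male,TRUE,20.3,85.3,90.1,5.02,10.17,2.26,101.4,52.3,127.8,63.2,FALSE,0.151,FALSE,5
S0049,22.4,female,FALSE,24.5,81.2,90,5.22,5.63,1.25,98.3,56.3,112.1,83.7,FALSE,0.569,FALSE,5
S0050,59.7,female,TRUE,28,83.7,86.6,5.06,4.16,0.89,63.5,68.4,134.4,92.4,FALSE,1.577,FALSE,5
S0051,47.7,female,TRUE,23.9,79.2,92.8,5.07,6.77,1.55,151.8,59.6,125.7,80.4,TRUE,3.161,FALSE,5
S0052,44.9,female,TRUE,22.1,95.7,86.1,5.59,13.76,2.93,138.2,47.7,99.4,63.7,FALSE,5.288,FALSE,5
S0053,71.3,female,TRUE,33,112.4,89.4,5.26,44.13,9.74,306.3,64.1,140.7,84.1,TRUE,13.53,TRUE,4
S0054,35.5,female,TRUE,21.1,94.7,75.1,5.15,6.53,1.21,117.3,71.7,88.3,74.9,FALSE,0.083,FALSE,5
S0055,59.4,female,TRUE,31.4,92,91.5,5.44,63.91,14.44,88.9,40.3,128.1,84.1,FALSE,2.538,TRUE,3
S0056,54.7,female,FALSE,26.8,88.9,82.2,5.57,8.23,1.67,85.6,48.1,114.2,74.1,TRUE,1.354,FALSE,5
S0057,34.1,male,TRUE,26.7,97.4,98,5.3,6.22,1.51,219.5,51.1,148.1,74.4,TRUE,2.992,FALSE,5
S0058,65.5,female,FALSE,34.1,70,82.1,5.48,6.1,1.24,122.6,52,121,64.7,FALSE,0.297,FALSE,5
S0059,28.1,male,FALSE,24.2,97,83.5,5.48,7.55,1.56,62.7,28.9,134.7,85.1,FALSE,0.09,FALSE,5
S0060,41.6,female,TRUE,23.6,91,73.6,4.67,20.73,3.77,65.4,56,117.2,71.3,FALSE,1.155,FALSE,5
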