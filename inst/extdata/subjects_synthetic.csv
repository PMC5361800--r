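id,timepoint,age_years,height_cm,weight_kg,sinus_mm,proximal_DAo_mm,wss_prox_inner_dao,max_velocity_aao,helix_vortex_grade
P01,t1,15,193.6,47,30.8,25,0.83,1.73,2
P02,t1,15.1,176.7,50.3,31.1,22.5,0.698,1.48,1
P03,t1,10.8,186.5,55.4,30.6,22.4,0.555,1.63,0
P04,t1,13.3,187.7,45,31.4,22,0.038,1.34,0
P05,t1,14.6,204.2,54.1,29.7,19.3,0.886,1.24,0
P06,t1,13,189.6,50.8,29.8,21.9,0.555,1.37,2
P07,t1,14.4,196.9,57.9,34.5,16.9,0.764,1.4,1
P08,t1,9.1,194.1,58.5,31.4,20.1,0.643,1.62,2
P09,t1,8.9,182.7,47.6,30.6,20.5,0.609,1.78,1
P10,t1,13.8,184,44.7,31.3,24.3,0.47,1.55,4
P11,t1,11.5,179.1,49.1,30.5,21.9,0.489,1.4,4
P12,t1,11.2,184.1,42.1,23.7,21.1,0.636,1.7,3
P13,t1,11.7,181.5,44.8,28.1,20.1,0.102,1.47,1
P14,t1,8.8,182.1,34.5,32.4,23.2,0.569,1.66,2
P15,t1,15.4,212.1,60.9,30.5,28,0.506,1.31,2
P16,t1,15,203.5,69.2,35.8,24.7,0.399,1.32,2
P17,t1,15.7,203.7,67.2,33.1,23,0.61,1.62,1
P18,t1,11.1,177.5,60.9,26.8,23.8,0.96,1.74,4
P19,t1,12,183.7,64.3,30.1,20.5,0.537,1.74,2
P01,t2,18.5,207,44.2,30,25.5,0.77,1.37,3
P02,t2,18.6,186.2,54.4,30.9,25.2,0.74,1.72,2
P03,t2,14.3,189.9,72.4,32.2,28.9,0.486,1.52,0
P04,t2,16.8,201.7,51,30.8,22.3,-0.046,1.24,0
P05,t2,18.1,217.9,65.7,33.6,26.6,0.965,1.24,1
P06,t2,16.5,198.6,62.9,29.3,23.2,0.466,1.25,2
P07,t2,17.9,208.5,69.5,35.6,27.9,0.589,1.25,2
P08,t2,12.6,206,65,33.1,25.2,0.597,1.47,2
P09,t2,12.4,192.7,64.8,33.5,26.2,0.512,1.67,1
P10,t2,17.3,190,59.8,30.7,27.3,0.428,1.31,4
P11,t2,15,178.5,56,31.2,24.6,0.388,1.46,4
P12,t2,14.7,200.7,48.5,33.1,22.8,0.6,1.64,4
P13,t2,15.2,193.2,55.8,30.3,25.9,0.095,1.23,2
P14,t2,12.3,191.2,39.2,31.6,26,0.469,1.72,2
P15,t2,18.9,216.4,74.2,34,29.3,0.478,1.16,3
P16,t2,18.5,215.7,81,35.2,23.1,0.388,1.13,2
P17,t2,19.2,207.3,71.9,34.2,29.1,0.481,1.45,1
P18,t2,14.6,173.9,72.5,32.8,23.4,0.904,1.59,4
P19,t2,15.5,186.3,71.6,32.9,26.5,0.531,1.55,2
V01,volunteer,20.8,182.6,73.8,32.4,17.3,0.886,1.65,0
V02,volunteer,28.6,164.7,69.8,33.2,19.3,0.737,1.47,0
V03,volunteer,20.8,172,67.3,29.1,18.3,0.804,1.55,0
V04,volunteer,24.4,168.4,79.2,32.3,17.5,0.613,1.19,0
V05,volunteer,27.8,165.1,64.4,29.5,19.7,0.685,1.35,0
V06,volunteer,27.6,186.5,61.2,30.3,17.6,0.854,1.38,0
V07,volunteer,25.5,171.4,60,31.2,17.8,0.881,1.38,0
V08,volunteer,20.6,172.3,58.6,27.9,15.4,0.592,1.38,0
V09,volunteer,24.6,177.8,54.1,28.7,18.6,0.835,1.51,0
V10,volunteer,22.8,176.8,58.7,27.3,17.7,0.982,1.37,0
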