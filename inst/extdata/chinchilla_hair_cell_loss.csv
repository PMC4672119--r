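group,laeq,ohc_500,ohc_1000,ohc_2000,ohc_4000,ohc_8000,ohc_16000,ihc_500,ihc_1000,ihc_2000,ihc_4000,ihc_8000,ihc_16000
G44,100.6,20.8,38.1,67.9,67.5,62.7,42.7,1.6,5.6,22.8,21,22.7,6.9
G49,101,43.8,54.6,78.3,93.1,79.3,71.7,2.1,4.6,24.8,63.9,29.5,26.7
G50,100.5,11.8,21.7,15,12.7,28,25.6,0.7,2.6,2,4.7,12.3,10.7
G51,100.1,32.6,30.9,43.9,49.7,27,13.8,3.1,6.6,9.6,21.2,5,4
G52,101.7,39.1,40.8,64.7,66.3,41,20.5,3.4,6.8,18.8,35.6,7.6,6.9
G53,100.6,27.8,39.3,50.7,67.6,49.9,32.1,1,4,7.5,23.3,14.2,5
G54,100.6,21,23.7,60.4,69.9,35.1,17.8,1.1,1.8,22.1,22.7,11.9,9.4
G55,100.1,40.7,36.4,55.5,80.4,89.9,80.5,6.7,9.7,7.8,28.3,75.2,38.9
G60,100.2,35,34.2,54.1,72.4,47.5,29.5,2.1,2.4,22.6,32.1,11.3,12.3
G61,99.6,7.9,5.6,4.6,9.9,14.3,17.2,0.2,0.2,0.2,2.8,2.6,8.1
G63,99.6,35.6,50.1,65.8,75.6,42.3,36.1,5.1,17.3,26.2,26.2,10.2,11
G64,101.1,15.6,11.3,25.7,50.8,16,14.5,0.6,0.6,3.4,16.7,6.1,9.1
G65,99.7,24,16.7,25.1,71.3,90,46.7,1.5,1.8,1.4,15.4,61.6,22.9
G66,100.7,21.3,11.2,12.9,60.5,82.7,37.9,0.8,1,0.6,12.9,56.2,16.5
G68,99.7,22.8,22.4,30.5,70.4,89.9,58.9,1,1.6,7.7,23.8,52.3,15.9
G69,101,12.6,17.1,11.6,7.4,12.6,11.6,0.1,0.2,2.7,2.8,5.5,4.5
G70,100.7,23.4,19.9,52.2,89.6,46.1,38,0.7,0.9,8.8,50.7,18,16.4
G47,89.4,3.8,2.8,6.2,3.7,17,20.7,0.3,2.2,2.8,3.9,8.9,4
G48,91.7,5.9,4.6,2.5,5.8,9.7,15,0.4,0.4,1.5,2.7,4.6,9.5
G56,91.3,9,3.7,1.9,3.3,8.3,6.9,0.3,0.7,0.7,0.4,3.3,1.7
G57,94.2,28,24.2,15.7,10.2,13,16.7,0.4,0.6,2.5,3.2,5,11.6
G58,95.6,12.3,5.6,12.9,34.1,16.1,12.4,1,0.6,2.6,11,5.8,4.8
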