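sex,region,age_low,age_high,incidence_per_100k,mortality_per_100k
female,North,20,24,13.05,37.68
female,North,25,29,21.14,38.94
female,North,30,34,27.38,51.39
female,North,35,39,32.77,64.68
female,North,40,44,53.17,101.5
female,North,45,49,61.2,165.57
female,North,50,54,75.19,266.1
female,North,55,59,89.69,429.77
female,North,60,64,79.87,675.84
female,North,65,69,117.82,1101
female,North,70,74,124.84,1872.51
female,North,75,79,141.09,3248.98
female,North,80,84,163.27,5929.85
female,North,85,,154.04,14712.65
female,Midland,20,24,22.07,37.68
female,Midland,25,29,30.45,38.94
female,Midland,30,34,44.99,51.39
female,Midland,35,39,44.31,64.68
female,Midland,40,44,61.07,101.5
female,Midland,45,49,82.49,165.57
female,Midland,50,54,91.4,266.1
female,Midland,55,59,106.81,429.77
female,Midland,60,64,117.15,675.84
female,Midland,65,69,130.65,1101
female,Midland,70,74,152.85,1872.51
female,Midland,75,79,161.42,3248.98
female,Midland,80,84,174.31,5929.85
female,Midland,85,,176.49,14712.65
female,Central,20,24,8.57,37.68
female,Central,25,29,15.23,38.94
female,Central,30,34,26.69,51.39
female,Central,35,39,32.03,64.68
female,Central,40,44,48.73,101.5
female,Central,45,49,70.47,165.57
female,Central,50,54,71.11,266.1
female,Central,55,59,80.01,429.77
female,Central,60,64,85.87,675.84
female,Central,65,69,101.78,1101
female,Central,70,74,117.24,1872.51
female,Central,75,79,122.37,3248.98
female,Central,80,84,166.46,5929.85
female,Central,85,,139.02,14712.65
female,South,20,24,14.18,37.68
female,South,25,29,25.44,38.94
female,South,30,34,36.1,51.39
female,South,35,39,41.24,64.68
female,South,40,44,44.53,101.5
female,South,45,49,67.58,165.57
female,South,50,54,65.09,266.1
female,South,55,59,73.01,429.77
female,South,60,64,73.78,675.84
female,South,65,69,95.8,1101
female,South,70,74,97.26,1872.51
female,South,75,79,107.45,3248.98
female,South,80,84,112.9,5929.85
female,South,85,,140.24,14712.65
male,North,20,24,7.33,112.1
male,North,25,29,16.22,114.83
male,North,30,34,17.72,103.14
male,North,35,39,29.41,125.37
male,North,40,44,37.77,158.18
male,North,45,49,55.79,232.2
male,North,50,54,88.66,372.46
male,North,55,59,127.45,637.3
male,North,60,64,150.31,1074.51
male,North,65,69,184.56,1843.1
male,North,70,74,223.62,3180.72
male,North,75,79,260.94,5288.09
male,North,80,84,307.99,8937.2
male,North,85,,323.24,17857.8
male,Midland,20,24,11.64,112.1
male,Midland,25,29,20.84,114.83
male,Midland,30,34,26.78,103.14
male,Midland,35,39,34.8,125.37
male,Midland,40,44,49.91,158.18
male,Midland,45,49,75.69,232.2
male,Midland,50,54,95.82,372.46
male,Midland,55,59,116.35,637.3
male,Midland,60,64,161.28,1074.51
male,Midland,65,69,197.11,1843.1
male,Midland,70,74,239.07,3180.72
male,Midland,75,79,281.62,5288.09
male,Midland,80,84,308.91,8937.2
male,Midland,85,,337.96,17857.8
male,Central,20,24,5.72,112.1
male,Central,25,29,9.42,114.83
male,Central,30,34,16.59,103.14
male,Central,35,39,23.81,125.37
male,Central,40,44,34.04,158.18
male,Central,45,49,49.06,232.2
male,Central,50,54,70.32,372.46
male,Central,55,59,89.78,637.3
male,Central,60,64,102.88,1074.51
male,Central,65,69,138.76,1843.1
male,Central,70,74,166.16,3180.72
male,Central,75,79,214.05,5288.09
male,Central,80,84,254.41,8937.2
male,Central,85,,239.09,17857.8
male,South,20,24,9.79,112.1
male,South,25,29,12.7,114.83
male,South,30,34,23.4,103.14
male,South,35,39,23.3,125.37
male,South,40,44,39.9,158.18
male,South,45,49,54.12,232.2
male,South,50,54,60.31,372.46
male,South,55,59,82.2,637.3
male,South,60,64,108.7,1074.51
male,South,65,69,120.67,1843.1
male,South,70,74,171.58,3180.72
male,South,75,79,190.06,5288.09
male,South,80,84,236.31,8937.2
male,South,85,,240.37,17857.8
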