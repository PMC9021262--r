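grouping,n_countries,shock_2020,prev_2019,prev_2021,wasted_2019,wasted_2021,change
Europe & Central Asia,11,-7.2,3.6,4.0,595327,649894,54567
Latin America & Caribbean,22,-9.3,2.8,3.2,1454980,1669074,214094
Middle East & N. Africa,12,-9.1,7.1,8.0,3166284,3364147,197863
East Asia excluding China,10,-9.2,7.8,9.1,5497099,6324098,826999
Sub-Saharan Africa,43,-6.5,7.7,8.4,13113190,14320514,1207324
South Asia excluding India,5,-6.0,12.4,13.7,5504399,5910794,406394
India,1,-14.9,20.8,26.3,24297263,30759634,6462371
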