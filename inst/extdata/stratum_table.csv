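study_area,stratum,count,proportion_pct,weight
CONUS,Developed,999,5.47,1.81
CONUS,Water,200,1.72,1.15
CONUS,Snow/Ice,30,0.01,45.02
CONUS,Barren,578,1.05,5.49
CONUS,Agriculture,1007,16.89,0.59
CONUS,Herbaceous Wetlands,659,1.44,4.56
CONUS,Shrub/Herb,1010,43.50,0.23
CONUS,Evergreen Loss,1280,4.37,2.91
CONUS,Evergreen Stable,988,11.99,0.82
CONUS,Deciduous West Loss,709,0.20,35.43
CONUS,Deciduous West Stable,533,0.81,6.55
CONUS,Deciduous East Loss,984,1.69,5.77
CONUS,Deciduous East Stable,990,10.79,0.91
CONUS,Volcanic Rocks,34,0.02,20.89
CONUS,S. Texas Coastal Wetlands,33,0.01,23.49
CONUS,S. Texas Oil & Gas,33,0.04,7.96
SEAK,Developed,30,0.36,8.89
SEAK,Water,30,2.80,1.15
SEAK,Snow/Ice,30,22.37,0.14
SEAK,Barren,80,10.95,0.79
SEAK,Herbaceous and Woody Wetlands,79,3.06,2.78
SEAK,Dwarf Shrub/Herbaceous,87,4.78,1.96
SEAK,Tall Shrub Stable,167,20.14,0.89
SEAK,Tree Stable,207,33.50,0.67
SEAK,Tree/Tall Shrub Loss,219,2.04,11.55
PRUSVI,Developed,157,14.14,1.01
PRUSVI,Water,30,1.10,2.47
PRUSVI,Barren,30,1.07,2.54
PRUSVI,Agriculture,76,3.36,2.05
PRUSVI,Non-Forested Wetland,76,0.69,9.95
PRUSVI,Forested Wetland,57,0.91,5.72
PRUSVI,Rangeland,200,34.32,0.53
PRUSVI,Evergreen,200,32.43,0.56
PRUSVI,Deciduous,114,8.44,1.23
PRUSVI,Cloud Forest,100,2.52,3.60
PRUSVI,Coastal Mixed Forest,60,1.00,5.47
HI,Developed,80,0.58,13.73
HI,Water,30,13.15,0.23
HI,Barren,50,20.54,0.24
HI,Agriculture,70,0.91,7.69
HI,Wetland,70,2.49,2.81
HI,Rangeland,150,12.52,1.20
HI,Forest,230,18.78,1.22
HI,Scrub shrub,120,12.00,1.00
HI,Loss,200,19.02,1.05
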