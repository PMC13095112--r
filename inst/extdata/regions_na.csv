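code,latMin,latMax,lonMin,lonMax
US-AL,30.2,35.0,-88.5,-84.9
US-AK,51.0,71.5,-179.9,-129.9
US-AZ,31.3,37.0,-114.8,-109.0
US-AR,33.0,36.5,-94.6,-89.6
US-CA,32.5,42.0,-124.4,-114.1
US-CO,37.0,41.0,-109.1,-102.0
US-CT,40.9,42.1,-73.7,-71.8
US-DE,38.4,39.8,-75.8,-75.0
US-DC,38.8,39.0,-77.1,-76.9
US-FL,24.5,31.0,-87.6,-80.0
US-GA,30.3,35.0,-85.6,-80.8
US-HI,18.9,22.3,-160.3,-154.8
US-ID,42.0,49.0,-117.2,-111.0
US-IL,36.9,42.5,-91.5,-87.0
US-IN,37.8,41.8,-88.1,-84.8
US-IA,40.4,43.5,-96.6,-90.1
US-KS,37.0,40.0,-102.1,-94.6
US-KY,36.5,39.1,-89.6,-81.9
US-LA,28.9,33.0,-94.0,-88.8
US-ME,43.0,47.5,-71.1,-66.9
US-MD,37.9,39.7,-79.5,-75.0
US-MA,41.2,42.9,-73.5,-69.9
US-MI,41.7,48.3,-90.4,-82.4
US-MN,43.5,49.4,-97.2,-89.5
US-MS,30.2,35.0,-91.7,-88.1
US-MO,36.0,40.6,-95.8,-89.1
US-MT,44.4,49.0,-116.1,-104.0
US-NE,40.0,43.0,-104.1,-95.3
US-NV,35.0,42.0,-120.0,-114.0
US-NH,42.7,45.3,-72.6,-70.6
US-NJ,38.9,41.4,-75.6,-73.9
US-NM,31.3,37.0,-109.1,-103.0
US-NY,40.5,45.0,-79.8,-71.9
US-NC,33.8,36.6,-84.3,-75.5
US-ND,45.9,49.0,-104.1,-96.6
US-OH,38.4,42.0,-84.8,-80.5
US-OK,33.6,37.0,-103.0,-94.4
US-OR,42.0,46.3,-124.6,-116.5
US-PA,39.7,42.3,-80.5,-74.7
US-RI,41.1,42.0,-71.9,-71.1
US-SC,32.0,35.2,-83.4,-78.5
US-SD,42.5,45.9,-104.1,-96.4
US-TN,35.0,36.7,-90.3,-81.6
US-TX,25.8,36.5,-106.6,-93.5
US-UT,37.0,42.0,-114.1,-109.0
US-VT,42.7,45.0,-73.4,-71.5
US-VA,36.5,39.5,-83.7,-75.2
US-WA,45.5,49.0,-124.8,-116.9
US-WV,37.2,40.6,-82.6,-77.7
US-WI,42.5,47.1,-92.9,-86.8
US-WY,41.0,45.0,-111.1,-104.0
CA-AB,49.0,60.0,-120.0,-110.0
CA-BC,48.3,60.0,-139.1,-114.0
CA-MB,49.0,60.0,-102.0,-89.0
CA-NB,44.6,48.1,-69.1,-63.8
CA-NL,46.6,60.4,-67.8,-52.6
CA-NS,43.4,47.1,-66.4,-59.7
CA-NT,60.0,78.8,-136.5,-102.0
CA-NU,60.0,83.1,-120.7,-61.1
CA-ON,41.7,56.9,-95.2,-74.3
CA-PE,45.9,47.1,-64.4,-62.0
CA-QC,45.0,62.6,-79.8,-57.1
CA-SK,49.0,60.0,-110.0,-101.4
CA-YT,60.0,69.6,-141.0,-124.0
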