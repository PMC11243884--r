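{
 "x16": [
  0.058227,
  0.519076,
  -0.204396,
  0.847654,
  0.070824,
  2.442306,
  -2.156512,
  -0.885432,
  1.895885,
  1.16167,
  0.667999,
  1.161684,
  1.506095,
  0.67999,
  0.329959,
  -0.446895
 ],
 "cases": [
  {
   "wavelet": "db2",
   "dwt_a": [
    -0.024327385032821697,
    0.26054501698073357,
    1.2951319779528245,
    -1.0682239526861257,
    1.332243669934209,
    1.1853168920288408,
    1.9306390634497863,
    0.4967221321959474
   ],
   "dwt_d": [
    0.5777124680501597,
    0.6535117582925167,
    2.958974840728943,
    -1.48900915866326,
    0.33876948665423856,
    -0.05567946265138499,
    -0.07845016921375988,
    -0.5639119028974807
   ],
   "wavedec2_a2": [
    0.11034527077884587,
    0.7973917295177184,
    0.614369431986429,
    2.301960567717007
   ],
   "wavedec2_d2": [
    -0.46637829820422866,
    -1.8610239337288161,
    -0.10126605869500085,
    -0.15886681379008433
   ],
   "wavedec2_d1": [
    0.5777124680501597,
    0.6535117582925167,
    2.958974840728943,
    -1.48900915866326,
    0.33876948665423856,
    -0.05567946265138499,
    -0.07845016921375988,
    -0.5639119028974807
   ]
  },
  {
   "wavelet": "sym4",
   "dwt_a": [
    0.3644402041450294,
    0.6800286990498772,
    0.7287465863135318,
    -0.7115033882888099,
    1.8759860499779277,
    1.6692812989829742,
    1.0819139828092488,
    -0.2808460181645123
   ],
   "dwt_d": [
    -0.18955922696586902,
    0.7563820355051031,
    0.7830593211039715,
    2.774694487276298,
    -1.8642380229038744,
    0.6406907560314832,
    -0.46161442689555443,
    -0.0974970628559132
   ],
   "wavedec2_a2": [
    0.9647234577999804,
    0.3661684078600845,
    2.502857255585082,
    -0.009682121245347806
   ],
   "wavedec2_d2": [
    -0.3037047040927397,
    -0.29694256055906326,
    -1.2954342849854033,
    -0.00895337814958834
   ],
   "wavedec2_d1": [
    -0.18955922696586902,
    0.7563820355051031,
    0.7830593211039715,
    2.774694487276298,
    -1.8642380229038744,
    0.6406907560314832,
    -0.46161442689555443,
    -0.0974970628559132
   ]
  },
  {
   "wavelet": "coif1",
   "dwt_a": [
    0.07600887392707946,
    0.27974218725786903,
    1.4723376965621342,
    -1.5153346422262879,
    1.8543554889160665,
    1.1510535137373852,
    1.8727013792362452,
    0.21718291741290313
   ],
   "dwt_d": [
    -0.46522257567735326,
    -0.562942170259263,
    -2.783212181033966,
    0.8265618119967602,
    0.018821749302254068,
    -0.12015666603300006,
    0.15292541395180842,
    0.5913067574527879
   ],
   "wavedec2_a2": [
    0.026281786217041136,
    0.6081780829233842,
    1.2652499951589977,
    1.9243571357005775
   ],
   "wavedec2_d2": [
    0.1645157687686136,
    2.588040869464708,
    0.24763314604893943,
    0.6362903056342458
   ],
   "wavedec2_d1": [
    -0.46522257567735326,
    -0.562942170259263,
    -2.783212181033966,
    0.8265618119967602,
    0.018821749302254068,
    -0.12015666603300006,
    0.15292541395180842,
    0.5913067574527879
   ]
  },
  {
   "wavelet": "bior2.2",
   "dwt_a": [
    0.06508228491710512,
    0.24360411974971047,
    1.6556502230617733,
    -2.084556624568887,
    2.371689000331574,
    0.928558836471941,
    2.0721693511993653,
    0.15585022366081158
   ],
   "dwt_d": [
    -0.4187207051008166,
    -0.6466067249882266,
    -2.464373198452296,
    0.533949411949414,
    0.08504514678686848,
    -0.05277632882742034,
    0.16831757687330218,
    0.45324696145920274
   ],
   "wavedec2_a2": [
    -0.448733,
    0.6744428749999997,
    1.4478574999999994,
    2.1504996249999997
   ],
   "wavedec2_d2": [
    0.43611668749999993,
    2.8978835625,
    0.9145509374999998,
    0.6454298125
   ],
   "wavedec2_d1": [
    -0.4187207051008166,
    -0.6466067249882266,
    -2.464373198452296,
    0.533949411949414,
    0.08504514678686848,
    -0.05277632882742034,
    0.16831757687330218,
    0.45324696145920274
   ]
  },
  {
   "wavelet": "rbio3.1",
   "dwt_a": [
    0.1910280789180611,
    0.44541964294485825,
    1.1014128568999453,
    -0.8463433542466858,
    1.5830763185746919,
    1.4419346230693417,
    1.4230343659150066,
    0.06848488274817484
   ],
   "dwt_d": [
    0.5745405231700371,
    0.9573865192807447,
    1.4532034302877208,
    1.1549949339045282,
    -0.22953181092062147,
    0.6454046434602092,
    -1.1702758649993599,
    -1.043804513883287
   ],
   "wavedec2_a2": [
    0.54433803125,
    0.49386184374999986,
    1.7061998437499997,
    1.0796672812499999
   ],
   "wavedec2_d2": [
    0.6350181875,
    -1.6636850624999995,
    0.6526428125000003,
    -1.8789789375
   ],
   "wavedec2_d1": [
    0.5745405231700371,
    0.9573865192807447,
    1.4532034302877208,
    1.1549949339045282,
    -0.22953181092062147,
    0.6454046434602092,
    -1.1702758649993599,
    -1.043804513883287
   ]
  }
 ]
}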