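"channel","region_id","region","probability"
1,21,"Middle temporal gyrus",100
2,21,"Middle temporal gyrus",51.22
3,37,"Fusiform gyrus",67.43
4,48,"Retrosubicular area",52.17
5,21,"Middle temporal gyrus",75.77
6,21,"Middle temporal gyrus",44.35
7,37,"Fusiform gyrus",76.97
8,43,"Subcentral area",41.39
9,22,"Superior temporal gyrus",71.33
10,37,"Fusiform gyrus",56.27
11,6,"Premotor and supplementary motor cortex",71.65
12,43,"Subcentral area",45.88
13,22,"Superior temporal gyrus",65.67
14,37,"Fusiform gyrus",44.92
15,43,"Subcentral area",38.89
16,2,"Primary somatosensory cortex",45.13
17,39,"Angular gyrus part of Wernicke’s area",35.12
18,6,"Premotor and supplementary motor cortex",63.53
19,1,"Primary somatosensory cortex",41.8
20,40,"Supramarginal gyrus part of Wernicke’s area",99.03
21,39,"Angular gyrus part of Wernicke’s area",88.31
22,6,"Premotor and supplementary motor cortex",72.12
23,1,"Primary somatosensory cortex",34.7
24,40,"Supramarginal gyrus part of Wernicke’s area",56.65
25,37,"Fusiform gyrus",55.38
26,20,"Inferior temporal gyrus",53.94
27,21,"Middle temporal gyrus",92.39
28,37,"Fusiform gyrus",73.22
29,20,"Inferior temporal gyrus",43.51
30,21,"Middle temporal gyrus",79.24
31,48,"Retrosubicular area",37.43
32,37,"Fusiform gyrus",54.31
33,22,"Superior temporal gyrus",59.7
34,48,"Retrosubicular area",32.33
35,37,"Fusiform gyrus",48
36,22,"Superior temporal gyrus",66.06
37,43,"Subcentral area",42.03
38,6,"Premotor and supplementary motor cortex",47.02
39,39,"Angular gyrus part of Wernicke’s area",31.96
40,2,"Primary somatosensory cortex",53.54
41,43,"Subcentral area",34.46
42,39,"Angular gyrus part of Wernicke’s area",92.37
43,40,"Supramarginal gyrus part of Wernicke’s area",91.28
44,3,"Primary somatosensory cortex",35.89
45,6,"Premotor and supplementary motor cortex",60.48
46,40,"Supramarginal gyrus part of Wernicke’s area",49.49
47,40,"Supramarginal gyrus part of Wernicke’s area",31.53
48,6,"Premotor and supplementary motor cortex",77.27
49,10,"Frontopolar area",38.11
50,10,"Frontopolar area",66.27
51,11,"Orbitofrontal area",47.76
52,46,"Dorsolateral prefrontal cortex",50.79
53,46,"Dorsolateral prefrontal cortex",68.29
54,10,"Frontopolar area",84.28
55,10,"Frontopolar area",100
56,10,"Frontopolar area",78.15
57,46,"Dorsolateral prefrontal cortex",54.73
58,46,"Dorsolateral prefrontal cortex",78.9
59,10,"Frontopolar area",81.39
60,10,"Frontopolar area",71.98
61,46,"Dorsolateral prefrontal cortex",75.66
62,45,"pars triangularis Broca’s area",52.72
63,9,"Dorsolateral prefrontal cortex",64.27
64,9,"Dorsolateral prefrontal cortex",68.93
65,9,"Dorsolateral prefrontal cortex",54.39
66,45,"pars triangularis Broca’s area",69.66
67,9,"Dorsolateral prefrontal cortex",83.33
68,9,"Dorsolateral prefrontal cortex",85.37
69,9,"Dorsolateral prefrontal cortex",92.34
70,9,"Dorsolateral prefrontal cortex",76.67
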