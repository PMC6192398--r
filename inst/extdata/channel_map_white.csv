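"channel","region_id","region","probability"
1,21,"Middle temporal gyrus",100
2,21,"Middle temporal gyrus",64.71
3,37,"Fusiform gyrus",59.39
4,48,"Retrosubicular area",44.02
5,21,"Middle temporal gyrus",57.62
6,21,"Middle temporal gyrus",44.67
7,37,"Fusiform gyrus",76.23
8,43,"Subcentral area",53.5
9,22,"Superior temporal gyrus",73.38
10,37,"Fusiform gyrus",39
11,6,"Premotor and supplementary motor cortex",50.87
12,2,"Primary somatosensory cortex",38.6
13,22,"Superior temporal gyrus",50.64
14,39,"Angular gyrus part of Wernicke’s area",34.66
15,6,"Premotor and supplementary motor cortex",34.58
16,40,"Supramarginal gyrus part of Wernicke’s area",40.89
17,40,"Supramarginal gyrus part of Wernicke’s area",38.82
18,6,"Premotor and supplementary motor cortex",68.82
19,1,"Primary somatosensory cortex",36.67
20,40,"Supramarginal gyrus part of Wernicke’s area",90.44
21,39,"Angular gyrus part of Wernicke’s area",71.37
22,6,"Premotor and supplementary motor cortex",63.07
23,3,"Primary somatosensory cortex",29.73
24,40,"Supramarginal gyrus part of Wernicke’s area",52.66
25,20,"Inferior temporal gyrus",55.92
26,21,"Middle temporal gyrus",56.38
27,21,"Middle temporal gyrus",100
28,37,"Fusiform gyrus",86.62
29,21,"Middle temporal gyrus",52.41
30,21,"Middle temporal gyrus",70.29
31,48,"Retrosubicular area",49.41
32,37,"Fusiform gyrus",38.22
33,22,"Superior temporal gyrus",71.51
34,43,"Subcentral area",44.68
35,37,"Fusiform gyrus",47.99
36,22,"Superior temporal gyrus",60.14
37,43,"Subcentral area",52.51
38,6,"Premotor and supplementary motor cortex",51.68
39,40,"Supramarginal gyrus part of Wernicke’s area",34.03
40,2,"Primary somatosensory cortex",54.93
41,6,"Premotor and supplementary motor cortex",38.32
42,39,"Angular gyrus part of Wernicke’s area",90.81
43,40,"Supramarginal gyrus part of Wernicke’s area",93.47
44,3,"Primary somatosensory cortex",36.82
45,6,"Premotor and supplementary motor cortex",61.93
46,40,"Supramarginal gyrus part of Wernicke’s area",63.27
47,3,"Primary somatosensory cortex",35.41
48,6,"Premotor and supplementary motor cortex",73.74
49,10,"Frontopolar area",58.57
50,10,"Frontopolar area",86.44
51,10,"Frontopolar area",69.98
52,46,"Dorsolateral prefrontal cortex",55.08
53,46,"Dorsolateral prefrontal cortex",79.07
54,10,"Frontopolar area",93.48
55,10,"Frontopolar area",100
56,10,"Frontopolar area",67.15
57,45,"pars triangularis Broca’s area",52.63
58,46,"Dorsolateral prefrontal cortex",83.37
59,10,"Frontopolar area",63.43
60,10,"Frontopolar area",49.58
61,46,"Dorsolateral prefrontal cortex",73.3
62,45,"pars triangularis Broca’s area",34.2
63,9,"Dorsolateral prefrontal cortex",88.24
64,9,"Dorsolateral prefrontal cortex",87.02
65,9,"Dorsolateral prefrontal cortex",64.57
66,45,"pars triangularis Broca’s area",51.54
67,9,"Dorsolateral prefrontal cortex",73.49
68,9,"Dorsolateral prefrontal cortex",65.34
69,9,"Dorsolateral prefrontal cortex",75.8
70,9,"Dorsolateral prefrontal cortex",69.88
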