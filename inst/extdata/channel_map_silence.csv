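"channel","region_id","region","probability"
1,21,"Middle temporal gyrus",100
2,20,"Inferior temporal gyrus",64.13
3,37,"Fusiform gyrus",75.99
4,48,"Retrosubicular area",52.96
5,21,"Middle temporal gyrus",77.64
6,20,"Inferior temporal gyrus",41.53
7,37,"Fusiform gyrus",74.41
8,43,"Subcentral area",38.1
9,22,"Superior temporal gyrus",69.63
10,37,"Fusiform gyrus",57.63
11,6,"Premotor and supplementary motor cortex",53.79
12,43,"Subcentral area",41.53
13,22,"Superior temporal gyrus",60.56
14,37,"Fusiform gyrus",46.9
15,6,"Premotor and supplementary motor cortex",41.73
16,40,"Supramarginal gyrus part of Wernicke’s area",41.06
17,39,"Angular gyrus part of Wernicke’s area",35.06
18,6,"Premotor and supplementary motor cortex",58.1
19,1,"Primary somatosensory cortex",33.77
20,40,"Supramarginal gyrus part of Wernicke’s area",85.84
21,39,"Angular gyrus part of Wernicke’s area",85.81
22,6,"Premotor and supplementary motor cortex",69.99
23,3,"Primary somatosensory cortex",27.51
24,40,"Supramarginal gyrus part of Wernicke’s area",53.97
25,37,"Fusiform gyrus",60.2
26,20,"Inferior temporal gyrus",74.03
27,21,"Middle temporal gyrus",100
28,37,"Fusiform gyrus",86.5
29,20,"Inferior temporal gyrus",59.84
30,21,"Middle temporal gyrus",85.23
31,48,"Retrosubicular area",50.6
32,37,"Fusiform gyrus",54.7
33,22,"Superior temporal gyrus",62.7
34,48,"Retrosubicular area",37.04
35,37,"Fusiform gyrus",54.66
36,22,"Superior temporal gyrus",70.4
37,43,"Subcentral area",54.95
38,44,"pars opercularis part of Broca’s area",54.77
39,22,"Superior temporal gyrus",31.82
40,2,"Primary somatosensory cortex",58.17
41,6,"Premotor and supplementary motor cortex",44.97
42,39,"Angular gyrus part of Wernicke’s area",86.18
43,40,"Supramarginal gyrus part of Wernicke’s area",92.18
44,3,"Primary somatosensory cortex",36.57
45,9,"Dorsolateral prefrontal cortex",46.15
46,40,"Supramarginal gyrus part of Wernicke’s area",63.65
47,3,"Primary somatosensory cortex",37.31
48,6,"Premotor and supplementary motor cortex",86.86
49,10,"Frontopolar area",40.46
50,10,"Frontopolar area",56.98
51,10,"Frontopolar area",53.9
52,46,"Dorsolateral prefrontal cortex",48.84
53,46,"Dorsolateral prefrontal cortex",64.32
54,10,"Frontopolar area",82.16
55,10,"Frontopolar area",100
56,10,"Frontopolar area",58.96
57,45,"pars triangularis Broca’s area",60.12
58,46,"Dorsolateral prefrontal cortex",93.75
59,10,"Frontopolar area",86.26
60,10,"Frontopolar area",61.04
61,46,"Dorsolateral prefrontal cortex",64.66
62,45,"pars triangularis Broca’s area",52.48
63,9,"Dorsolateral prefrontal cortex",77.96
64,9,"Dorsolateral prefrontal cortex",82.9
65,9,"Dorsolateral prefrontal cortex",57.12
66,45,"pars triangularis Broca’s area",56.37
67,9,"Dorsolateral prefrontal cortex",92.39
68,9,"Dorsolateral prefrontal cortex",90.94
69,9,"Dorsolateral prefrontal cortex",90.21
70,9,"Dorsolateral prefrontal cortex",69.97
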