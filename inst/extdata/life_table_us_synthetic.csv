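# Synthetic unisex life table, ages 55-85.
# qx = annual probability of death. SYNTHETIC: log-linear (Gompertz-type)
# interpolation through US-magnitude anchor values at 5-year ages; stands in
# for a published national life table and is swappable via load_life_table().
age,qx
55,0.00817
56,0.00873
57,0.00932
58,0.00996
59,0.01064
60,0.01136
61,0.01216
62,0.01301
63,0.01392
64,0.01490
65,0.01594
66,0.01720
67,0.01855
68,0.02001
69,0.02159
70,0.02329
71,0.02544
72,0.02780
73,0.03037
74,0.03317
75,0.03624
76,0.03988
77,0.04388
78,0.04828
79,0.05313
80,0.05846
81,0.06486
82,0.07196
83,0.07983
84,0.08857
85,0.09826
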