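# Synthetic motoneuron density table (counts per 100 um bin, one side).
# Pinned constraints: 25 rostral bins (0.5-3.0 mm) sum to 248; 18 caudal
# bins (3.0-4.8 mm) are non-increasing from 4 to 2 per 100 um and sum to 63;
# full-roster total 311 per side. Per-bin values are a synthetic
# digitization, not measured counts.
bin_start_mm,bin_end_mm,count
0.5,0.6,6
0.6,0.7,8
0.7,0.8,10
0.8,0.9,11
0.9,1.0,12
1.0,1.1,12
1.1,1.2,12
1.2,1.3,12
1.3,1.4,12
1.4,1.5,12
1.5,1.6,11
1.6,1.7,11
1.7,1.8,11
1.8,1.9,11
1.9,2.0,10
2.0,2.1,10
2.1,2.2,10
2.2,2.3,10
2.3,2.4,9
2.4,2.5,9
2.5,2.6,9
2.6,2.7,8
2.7,2.8,8
2.8,2.9,7
2.9,3.0,7
3.0,3.1,4
3.1,3.2,4
3.2,3.3,4
3.3,3.4,4
3.4,3.5,4
3.5,3.6,4
3.6,3.7,4
3.7,3.8,4
3.8,3.9,4
3.9,4.0,4
4.0,4.1,4
4.1,4.2,3
4.2,4.3,3
4.3,4.4,3
4.4,4.5,3
4.5,4.6,3
4.6,4.7,2
4.7,4.8,2
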