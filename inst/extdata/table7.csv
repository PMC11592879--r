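TLE Patient No,Expert Findings from EEG,Expert Findings from MRI,Decision of Analysis-1,Decision of Analysis-2,Decision of Analysis-3,Decision Tree Final Result
1,Right TLE,Right Mesial Temporal Sclerosis,NaN,Right TLE,Right TLE,Right TLE
2,Left TLE,Right Hippocampal Sclerosis,Right TLE,Left TLE,Left TLE,Left TLE
3,Left TLE,MRI-negative,Left TLE,Left TLE,Left TLE,Left TLE
4,Right TLE,MRI-negative,Right TLE,MRI negative,Left TLE,Right TLE
5,Right TLE,MRI-negative,Right TLE,Right TLE,Right TLE,Right TLE
6,Right TLE,MRI-negative,Right TLE,Right TLE,Right TLE,Right TLE
7,Left TLE,MRI-negative,Left TLE,Left TLE,Left TLE,Left TLE
8,Right TLE,Bilateral Hippocampal Atrophy,Right TLE,Left TLE,Right TLE,Right TLE
9,Right TLE,Bilateral Hippocampal Atrophy,Right TLE,Right TLE,Right TLE,Right TLE
10,Right TLE,MRI-negative,Left TLE,Right TLE,Right TLE,Right TLE
11,Left TLE,Left Hippocampal Atrophy,Left TLE,Left TLE,Left TLE,Left TLE
12,Left TLE,MRI-negative,Right TLE,Left TLE,Left TLE,Left TLE
13,Right TLE,Right Hippocampal Atrophy,Right TLE,MRI negative,Left TLE,Right TLE
14,Right TLE,MRI-negative,Right TLE,MRI negative,Right TLE,Right TLE
15,Left TLE,MRI-negative,Left TLE,Left TLE,Left TLE,Left TLE
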