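marker_id	chromosome	position
C1M1S	chr1	1e+06
C1M1E	chr1	1e+07
C1M2S	chr1	10500000
C1M2E	chr1	2.5e+07
C1M3S	chr1	25500000
C1M3E	chr1	6e+07
C1M4S	chr1	60500000
C1M4E	chr1	9e+07
C2M1S	chr2	1e+06
C2M1E	chr2	1e+07
C2M2S	chr2	10500000
C2M2E	chr2	2.5e+07
C2M3S	chr2	25500000
C2M3E	chr2	6e+07
C2M4S	chr2	60500000
C2M4E	chr2	9e+07
C3M1S	chr3	1e+06
C3M1E	chr3	1e+07
C3M2S	chr3	10500000
C3M2E	chr3	2.5e+07
C3M3S	chr3	25500000
C3M3E	chr3	6e+07
C3M4S	chr3	60500000
C3M4E	chr3	9e+07
C4M1S	chr4	1e+06
C4M1E	chr4	1e+07
C4M2S	chr4	10500000
C4M2E	chr4	2.5e+07
C4M3S	chr4	25500000
C4M3E	chr4	6e+07
C4M4S	chr4	60500000
C4M4E	chr4	9e+07
C5M1S	chr5	1e+06
C5M1E	chr5	1e+07
C5M2S	chr5	10500000
C5M2E	chr5	2.5e+07
C5M3S	chr5	25500000
C5M3E	chr5	6e+07
C5M4S	chr5	60500000
C5M4E	chr5	9e+07
C6M1S	chr6	1e+06
C6M1E	chr6	1e+07
C6M2S	chr6	10500000
C6M2E	chr6	2.5e+07
C6M3S	chr6	25500000
C6M3E	chr6	6e+07
C6M4S	chr6	60500000
C6M4E	chr6	9e+07
C7M1S	chr7	1e+06
C7M1E	chr7	1e+07
C7M2S	chr7	10500000
C7M2E	chr7	2.5e+07
C7M3S	chr7	25500000
C7M3E	chr7	6e+07
C7M4S	chr7	60500000
C7M4E	chr7	9e+07
C8M1S	chr8	1e+06
C8M1E	chr8	1e+07
C8M2S	chr8	10500000
C8M2E	chr8	2.5e+07
C8M3S	chr8	25500000
C8M3E	chr8	6e+07
C8M4S	chr8	60500000
C8M4E	chr8	9e+07
C9M1S	chr9	1e+06
C9M1E	chr9	1e+07
C9M2S	chr9	10500000
C9M2E	chr9	2.5e+07
C9M3S	chr9	25500000
C9M3E	chr9	6e+07
C9M4S	chr9	60500000
C9M4E	chr9	9e+07
C10M1S	chr10	1e+06
C10M1E	chr10	1e+07
C10M2S	chr10	10500000
C10M2E	chr10	2.5e+07
C10M3S	chr10	25500000
C10M3E	chr10	6e+07
C10M4S	chr10	60500000
C10M4E	chr10	9e+07
C11M1S	chr11	1e+06
C11M1E	chr11	1e+07
C11M2S	chr11	10500000
C11M2E	chr11	2.5e+07
C11M3S	chr11	25500000
C11M3E	chr11	6e+07
C11M4S	chr11	60500000
C11M4E	chr11	9e+07
C12M1S	chr12	1e+06
C12M1E	chr12	1e+07
C12M2S	chr12	10500000
C12M2E	chr12	2.5e+07
C12M3S	chr12	25500000
C12M3E	chr12	6e+07
C12M4S	chr12	60500000
C12M4E	chr12	9e+07
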