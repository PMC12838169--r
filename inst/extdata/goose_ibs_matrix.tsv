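sample_id	YE.1	YE.2	YE.3	YE.4	YE.5	YE.6	YE.7	YE.8	YE.9	YE.10	YE.11	YE.12	YE.13	YE.14	YE.15
YE.1	0	0.22	0.23	0.23	0.31	0.23	0.24	0.26	0.31	0.23	0.23	0.24	0.25	0.23	0.16
YE.2	0.22	0	0.23	0.23	0.31	0.22	0.24	0.26	0.31	0.23	0.23	0.24	0.25	0.22	0.23
YE.3	0.23	0.23	0	0.24	0.31	0.23	0.24	0.26	0.31	0.24	0.24	0.22	0.25	0.24	0.24
YE.4	0.23	0.23	0.24	0	0.31	0.24	0.24	0.27	0.31	0.24	0.22	0.23	0.23	0.22	0.23
YE.5	0.31	0.31	0.31	0.31	0	0.31	0.31	0.30	0.25	0.31	0.31	0.31	0.31	0.31	0.31
YE.6	0.23	0.22	0.23	0.24	0.31	0	0.20	0.26	0.31	0.22	0.24	0.23	0.25	0.20	0.24
YE.7	0.24	0.24	0.24	0.24	0.31	0.20	0	0.26	0.31	0.22	0.25	0.23	0.25	0.23	0.24
YE.8	0.26	0.26	0.26	0.27	0.30	0.26	0.26	0	0.30	0.26	0.25	0.23	0.24	0.25	0.23
YE.9	0.31	0.31	0.31	0.31	0.25	0.31	0.31	0.30	0	0.31	0.31	0.31	0.31	0.31	0.31
YE.10	0.23	0.23	0.24	0.24	0.31	0.22	0.22	0.26	0.31	0	0.23	0.24	0.25	0.22	0.23
YE.11	0.23	0.23	0.24	0.22	0.31	0.24	0.25	0.25	0.31	0.23	0	0.22	0.25	0.24	0.23
YE.12	0.24	0.24	0.22	0.23	0.31	0.23	0.23	0.23	0.31	0.24	0.22	0	0.23	0.23	0.23
YE.13	0.25	0.25	0.25	0.23	0.31	0.25	0.25	0.24	0.31	0.25	0.25	0.23	0	0.23	0.25
YE.14	0.23	0.22	0.24	0.22	0.31	0.20	0.23	0.25	0.31	0.22	0.24	0.23	0.23	0	0.24
YE.15	0.16	0.23	0.24	0.23	0.31	0.24	0.24	0.23	0.31	0.23	0.23	0.23	0.25	0.24	0
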