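# nstsv	1
# kind	vanadium
# instrument	IN16
# sample	vanadium
# temperature_K	295
# monitor	1
# transmission	1
# reduction_state	raw
# q_units	inv_angstrom
# omega_units	ueV
q	intensity	sigma
0.19	113695	337.186891797413
0.279473684210526	112433	335.310304046863
0.368947368421053	110360	332.204756136934
0.458421052631579	108002	328.63657739211
0.547894736842105	105729	325.159960634762
0.637368421052632	102196	319.681091089229
0.726842105263158	99557	315.526544049784
0.816315789473684	96401	310.48510431259
0.90578947368421	94409	307.260475818157
0.995263157894737	91007	301.673664743875
1.08473684210526	88776	297.953016430443
1.17421052631579	87445	295.711007573272
1.26368421052632	86574	294.234600276718
1.35315789473684	85631	292.627749880287
1.44263157894737	84526	290.733554994947
1.53210526315789	85318	292.092451117793
1.62157894736842	86293	293.756702051204
1.71105263157895	87439	295.700862359243
1.80052631578947	89758	299.596395171905
1.89	91762	302.922432315601
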