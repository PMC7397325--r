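CCP_synthetic	synthetic 31-gene cell-cycle-progression stand-in	G000561	G000562	G000563	G000564	G000565	G000566	G000567	G000568	G000569	G000570	G000571	G000572	G000573	G000574	G000575	G000576	G000577	G000578	G000579	G000580	G000581	G000582	G000583	G000584	G000585	G000586	G000587	G000588	G000589	G000590	G000591
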