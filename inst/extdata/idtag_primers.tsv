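name	sequence	orientation
styr-ID1F	TTGAGCAGGAATAATTGGWACAT	forward
styr-ID1R	AAAAGCATGRGCTGTAACAA	reverse
styr-ID2F	TTGGAGGATTTGGTAATTGACTT	forward
styr-ID2R	AAAGATGGRGGTAATAATCAAAAT	reverse
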