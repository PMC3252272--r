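>ath-miR159a
UUUGGAUUGAAGGGAGCUCUA
>ath-miR159b
UUUGGAUUGAAGGGAGCUCUU
>ath-miR159c
UUUGGAUUGAAGGGAGCUCUC
>ath-miR319a
UUGGACUGAAGGGAGCUCCCU
>ath-miR319b
UUGGACUGAAGGGAGCUCCUU
>ath-miR319c
UUGGACUGAAGGGUGCUCCCU
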