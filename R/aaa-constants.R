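# Timing constants of the paradigm. Syllables last 250 ms, so words
# (three syllables) last 750 ms; the stimulation rates are their
# reciprocals: 4 Hz (syllable) and 1.333... Hz (word).

SYLLABLE_DURATION <- 0.25
WORD_DURATION <- 0.75
SYLLABLE_RATE <- 1 / SYLLABLE_DURATION
WORD_RATE <- 1 / WORD_DURATION
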