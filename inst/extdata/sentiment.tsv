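cue	role
recommend	positive
satisfied	positive
wonderful	positive
grateful	positive
pleased	positive
thumbs up	positive
disappointed	negative
terrible	negative
awful	negative
regret	negative
unhappy	negative
never again	negative
not	negation
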