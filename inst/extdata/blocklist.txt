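# Blocklist: terms removed from expanded BA categories during manual review.
# One term per line; '#' starts a comment. Versioned so the human-in-the-loop
# pruning step stays reproducible.
sucide        # misspelling of suicide; clinically wrong for activation
babydaddy
inactive      # antonym drawn in by distributional similarity
concerted
handsomeness
timeand       # corpus typo (run-together tokens)
independents
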