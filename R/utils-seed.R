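## Derive a well-separated 32-bit sub-seed from (base seed, stream id,
## replicate). Distinct streams keep the flag draw, the library-size draw
## and the count draw independent of each other across the grid.
.subSeed <- function(base, stream, replicate = 0L) {
    as.integer((as.numeric(base) * 2654435761 + stream * 40503 +
                as.numeric(replicate) * 2246822519) %% 2147483629)
}
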