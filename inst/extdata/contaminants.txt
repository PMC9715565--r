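# Default known-contaminant compositions removed during data reduction.
# One canonical formula per line; text after '#' is ignored.
# Common surfactants, plasticizers and lab-ware leachables seen in
# negative-mode ESI of methanolic SPE extracts. Edit freely.
C12H26O4S   # dodecyl sulfate (SDS)
C24H38O4    # bis(2-ethylhexyl) phthalate
C16H22O4    # dibutyl phthalate
C12H14O4    # diethyl phthalate
C8H6O4      # phthalic acid
C18H34O2    # oleic acid (ubiquitous fatty-acid background)
C16H32O2    # palmitic acid
C12H24O2    # lauric acid
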