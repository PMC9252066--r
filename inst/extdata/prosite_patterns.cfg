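# PROSITE-syntax patterns for the ALDH active sites, keyed by accession.
# Shipped as editable configuration: transcribe/verify against the current
# PROSITE entries (https://prosite.expasy.org) before use on real proteomes.
# PS00687 = ALDH glutamic-acid active site; PS00070 = ALDH cysteine active site.
PS00687=[LIVMFGA]-E-[LIMSTAC]-[GS]-G-[KNLM]-[SADN]-[TAPFV]
PS00070=[FYLVA]-x-{GVEP}-x-G-[QE]-x-C-[LIVMGSTANC]-[AGCN]-{HE}-[GSTADNEKR]
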