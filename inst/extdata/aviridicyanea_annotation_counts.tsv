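database	count	percent_published
any	25594	97.09
Nr	25153	95.42
Nt	13072	49.59
SwissProt	18188	69.00
KEGG	21278	80.72
KOG	16660	63.20
GO	13441	50.99
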