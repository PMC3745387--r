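patient_id,ROE,EOR,LOE,EOL,LOR,ROL,VOE,EOV,VOR,ROV
RA003,,,---,,,,,,,
RA006,+++,---,,,,,,,,
RA010,,+++,,---,,,,,,
RA013,+++,---,,,,+++,,+++,,+++
RA015,,,,,,,,---,,---
RA016,,,,,,,,,,
RA019,,,---,,---,,,,,
RA026,+++,,,,,,+++,,,
RA028,---,,,,,,,---,,---
RA030,---,+++,,+++,+++,,---,,,
RA031,,,---,,,,,,,
RA032,---,,---,,---,,,,,
RA035,---,,,+++,,,,,,
RA040,,+++,,+++,,,,+++,,
RA041,,+++,+++,+++,+++,+++,,,+++,
RA042,,+++,,+++,,,+++,,,
RA046,,,,+++,,,,,,
RA052,,,,,,,,,,
RA053,,---,---,,---,,,+++,,+++
RA059,,,,+++,,+++,,,,
RA062,,,,,,,,,,
RA069,,,,,---,,,,,
RA100,+++,,,,,,,,,
RA104,,,,,,,,,,
RA111,,,,+++,,,,,,
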