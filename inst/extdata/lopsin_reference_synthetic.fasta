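>lopsin_reference_synthetic synthetic L-opsin reference, human-convention numbering; sites 180/197/233/277/285/308 carry S/H/S/Y/T/A
TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNY
KMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYRC
LNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATACISDFPNAWFRGSLHKKDVRS
YSAGMKYPFMRCGAQSHMVCLEYRHTFYVKMGLKWKMWELTNGRKLVHQNWLSCDCQSEG
YYMAQAEPGNHNFVHPCDARYMKLHWVNLKWRQDYLYTVWQTLFTVWWLSCEHAQYWNWG
NLHWCGKAGFQLRAKLTNAMEDGFLYCEYKQQDVLAIYFGQEKISNLQMCSQRTGWLPGA
MPLP
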