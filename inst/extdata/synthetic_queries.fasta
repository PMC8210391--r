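>demo_pos_0001 synthetic exosome-class
FFLEACGCHELAICAGAHICHKEGFDKCILGLDKDACADAFGIAFI
>demo_pos_0002 synthetic exosome-class
CFIHKFGHAKIFGLIDFKKHIIHLCCIICFEGHCKDADEEHKGLHGIDGGLFGFLICDE
>demo_pos_0003 synthetic exosome-class
FLHFECHILDGKELAKLLLGIIGIGIHHFKKICGFIDHGFCFHHFHAFGGIDFHAFHKAH
IGKA
>demo_pos_0004 synthetic exosome-class
LKEGFKEIEHIGHFALDGGDGHAACIGIDLADDGKKGIGILHCGEKLDGDAEKKFILFKL
>demo_pos_0005 synthetic exosome-class
DEFLFGGCHLKIFCAFIACEEIAKCIKCHKHEKKEGAKDLIDFKKKECFKEEDEC
>demo_pos_0006 synthetic exosome-class
DFDFLDALFELLICCLFADECLKFIECAICGAEGCLHFCKELGFGCFKFILDFCKAIDD
>demo_pos_0007 synthetic exosome-class
FLGHAHDFFHCIAKLFAKIELKCALCCKAKFDAHKADFHHDG
>demo_pos_0008 synthetic exosome-class
DLHACHELLFKALEHEECHIDIHAEADLGFDLFEKGFHGHKKALCFGFDFKHDEFIEHCF
IIDF
>demo_neg_0001 synthetic non-exosome-class
QNWQNMQTSMWWVPRVWTSYWRWSTPTPQYRYVNWYPPVMR
>demo_neg_0002 synthetic non-exosome-class
PNWQTWPPYMRPNWWSPVRPSTNMWVRWSMYSPYYWRMTNMNWPYWWVYSWTVMTYWQQW
MPSM
>demo_neg_0003 synthetic non-exosome-class
WYQRRRTNWMPSMQVPTTQVSNNPPYRVWMQQRNPWTRYSWPYVPMRSPTNRYMPRVPQY
TVYR
>demo_neg_0004 synthetic non-exosome-class
QYQPVWRMSNPYNNMMRSYWNWRVSRVSTWQWNTVNWQVWMVNVWYYVNPTPRWQV
>demo_neg_0005 synthetic non-exosome-class
NMNSQSWQQPYQPQRSQMRNWPWQPYMPQMQYRRRWQQPTMPMWNTSNYMRWPSSQYRVQ
V
>demo_neg_0006 synthetic non-exosome-class
MNWVPPVQTNRVPQQPYPWSMPPVWVWVWNPPNVVVRQWYRSMTQYSSTYSNMSRYWPMT
MTMST
>demo_neg_0007 synthetic non-exosome-class
YNQTSTMRVNYVSQYVTMPQQSWWPSQNMSVPQSPNQTQNYRPWWTRYVWQNRTRW
>demo_neg_0008 synthetic non-exosome-class
TWNWQTTRPQRPYMNMSVPWNQVSSQSQSQQQRVPVVWPYMV
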