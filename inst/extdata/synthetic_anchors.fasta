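>SYN_PAL_ANCHOR
HTCYRQYNQQPWNADITPVRCYHERNDELNGIGYKNKRFFKMDDWMCENVNCASVENQAV
EYMAIFAPPTKMKPMTTFRVPHFLYELDIVCCACMAITLVVDSTCCYQTWWFWDHSGSWL
AYQWGQQRSINQIHPYGGGVFHTRNPICNKIASGQQSSRHVEFTGAFMQLDDQPMPDWSD
HKRLTIPVCLEDGMHEWYLVLHPKIEYKTFWRMACVELVHKCMDWRNSIHNHYGWTFRRP
QYMSADKMSGSTMANSLDPHECYKHNALITWSKVLGGEELIFKQEPWRAKYGWFRFCIMF
>SYN_HAL_ANCHOR
ECWYFQNLIMEQYKNCVYQCVCDWDDRDRALRWPVWYVRPGLQRMMMGKTHHHGDTEWDI
LFVPCFKPTGCHCHTSEGQIVASHSRESLFYESNRDIHYHWYINYMNSVDIAYIQRCNVK
YCFGMTQEWNSEIIKFQCPQSRKWWGNANTTASGPWCAIMKTHDDDPFFKQYCVMWYWPD
NMAGMMYEETHWWKTQLPWPDELVMMTSYCIRVLFYARFANKMQTQTFRKFLVAKPHGDM
HICLEVHQIRASENPGAGGIFFESTKKILEKNLCVVHLNFSAALPRTSPAPGQGDLNHSR
>SYN_TAL_ANCHOR
TEKEPDCMRMFVWRPHEWCIPYGIDRRMVQVTHHVWVTLNSHKAIWIFQYKIQQTHDHWT
TFKICITKWKCNYACSPFRDLGHQIIPAHYKQYWMWDEDNMDFFWRTFEDSGLMRFKMIN
HAKWGPTPGKLRQAFMLYENCNHPKCVPSGWASGCAFMSMKPTVSFACGNYMYLQNWNAW
VYIVQPSLSCNDIRRTEQVIQAVQGNFFTFPERSTMGHSSSWCCSYPREKHLYNGCHHML
TRDCEAKDLIENQQDELYGWTRGDYALLAHSVENMNGFVDMPQCRKIEYVDVPLAAGLEY
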