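peptide	allele	source
KTYCVITCF	A0101	cellline1
CFTQGHNHF	A0101	cellline1
STMAFWMLF	A0101	cellline1
RTHKCPLGF	A0101	cellline1
GTKANNFAL	A0101	cellline1
ITCMNIWHF	A0101	cellline1
PTGYSSRKF	A0101	cellline1
ITEQPSWCF	A0101	cellline1
QTQKSIEVF	A0101	cellline1
NTGDTLHIF	A0101	cellline1
WTGFFTPRF	A0101	cellline1
STCERLYTF	A0101	cellline1
STIKLTPIT	A0101	cellline1
YTHCNIEAF	A0101	cellline1
MTYDLGEER	A0101	cellline1
PTLHAPSCF	A0101	cellline1
VTRPLWMNF	A0101	cellline1
GTYSTQPCF	A0101	cellline1
LTGSASDFF	A0101	cellline1
CAMIEFWTF	A0101	cellline1
STQKPIEHF	A0101	cellline1
ATPAKKVTF	A0101	cellline1
GTHRRRCNF	A0101	cellline1
RTGWEPAHF	A0101	cellline1
YTAIYHQNF	A0101	cellline1
TVDMRNGFF	A0101	cellline1
DTWLQWVDF	A0101	cellline1
KTGYEPGEF	A0101	cellline1
LTTIFLWRF	A0101	cellline1
RTMEYGPWF	A0101	cellline1
LTLHMSDLF	A0101	cellline1
ITVGHDSSF	A0101	cellline1
FTNPGHKIF	A0101	cellline1
FTMGWCVWF	A0101	cellline1
NTCGACVYF	A0101	cellline1
YTQPSRNLF	A0101	cellline1
GTITHPDIF	A0101	cellline1
VTNQECIAF	A0101	cellline1
CTAIMMKDF	A0101	cellline1
YTCFERKRF	A0101	cellline1
LTHCLHKAF	A0101	cellline1
LTMVVEMMF	A0101	cellline1
TTMRDDYSF	A0101	cellline1
ITLGWRCTF	A0101	cellline1
KTLARNKVF	A0101	cellline1
GTFTAYAGF	A0101	cellline1
DTYKGSRQF	A0101	cellline1
YKEDVGNQF	A0101	cellline1
TTTPWGSEA	A0101	cellline1
ETVRGLTHF	A0101	cellline1
DKGNVLSMF	A0101	cellline1
LTIKPQLLF	A0101	cellline1
RNHRMKKDF	A0101	cellline1
STNNDHLQF	A0101	cellline1
MTGDQTTFF	A0101	cellline1
TTRVASEYF	A0101	cellline1
RTHDPKKSF	A0101	cellline1
NTLSIPWWM	A0101	cellline1
RTVFLELVF	A0101	cellline1
PTLRGEFKR	A0101	cellline1
SIINFEKL	A0101	cellline1
SIINFEKXV	A0101	cellline1
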