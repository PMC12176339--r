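nt_direction,injunction_direction,nt_author,n
favorable,favorable,HIAE,68
favorable,favorable,other,47
unfavorable,unfavorable,HIAE,33
unfavorable,unfavorable,other,22
favorable,unfavorable,HIAE,9
favorable,unfavorable,other,8
unfavorable,favorable,HIAE,13
unfavorable,favorable,other,25
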