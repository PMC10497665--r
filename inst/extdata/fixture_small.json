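{"format":"nudgenet-session","version":"1","header":{"n_players":5,"inquiry_cost":1,"reply_cost":1,"reward":10,"endowment":100,"label":"F5","nudged":false,"suggestion_rounds":0,"seed":101,"n_rounds":3},"rounds":[{"round":1,"assignment":{"player_order":[1,5,2,4,3],"letter_order":["A","B","C","E","D"],"question":["A","C","D","E","B"],"expertise":["B","E","A","D","C"]},"inquiries":{"sender":[2,2,2,3,3,3,4,5,5,5,5],"receiver":[5,1,4,1,4,5,5,2,4,1,3]},"replies":{"sender":[1,1,4,4,5,5],"receiver":[2,5,2,3,2,3],"kind":["referral","self_expert","referral","self_expert","self_expert","referral"],"named_player":[5,null,5,null,null,4]}},{"round":2,"assignment":{"player_order":[5,2,4,1,3],"letter_order":["E","A","B","D","C"],"question":["D","A","C","B","E"],"expertise":["C","B","E","D","A"]},"inquiries":{"sender":[2,3,3,4,4,5,5],"receiver":[5,4,2,5,3,4,3]},"replies":{"sender":[3,4,5,5],"receiver":[5,5,2,4],"kind":["self_expert","referral","self_expert","referral"],"named_player":[null,3,null,2]}},{"round":3,"assignment":{"player_order":[2,1,4,3,5],"letter_order":["D","B","A","C","E"],"question":["B","D","C","A","E"],"expertise":["A","B","E","C","D"]},"inquiries":{"sender":[1,2,2,2,2,3,3,3,3,4,4,5,5,5],"receiver":[5,4,3,5,1,5,1,4,2,5,3,1,3,4]},"replies":{"sender":[1,1,3,3,4,4,5,5,5,5],"receiver":[2,5,2,5,2,3,1,2,3,4],"kind":["referral","referral","referral","self_expert","referral","self_expert","referral","self_expert","referral","referral"],"named_player":[5,3,5,null,5,null,2,null,4,1]}}]}
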